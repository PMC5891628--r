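// Event-driven complex-span trial engine.
//
// Semantics are identical to the R-level operations (encode / decay /
// interfere / restore / reactivate / retrieve / identify): association
// weights grow toward an asymptote while attended and decay exponentially
// otherwise; distractors distort the last-presented memorandum's
// working-memory copy by halfway averaging on shared feature units;
// refreshing cycles positions, reactivating bindings and restoring
// representations toward the closest long-term engram. Decay is applied
// lazily per weight row (exponential semigroup), which keeps a trial's cost
// proportional to the number of attentional events rather than to elapsed
// time. Retrieval noise for the (possibly many) candidates with exactly
// zero activation is drawn as the maximum of m i.i.d. Gaussians via the
// inverse-CDF of the maximum, which is distributionally identical to m
// individual draws; any such winner is below threshold anyway (an
// omission), so only the maximum matters.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double R, s, theta, sigma, D, Tr, Te, dstrength, repcap, cv;
  bool refresh_on;
};

Params read_params(const List& par) {
  Params p;
  p.R = as<double>(par["R"]);
  p.s = as<double>(par["s"]);
  p.theta = as<double>(par["theta"]);
  p.sigma = as<double>(par["sigma"]);
  double D = as<double>(par["D"]);
  p.D = as<bool>(par["decay_enabled"]) ? D : 0.0;
  p.Tr = as<double>(par["Tr"]);
  p.Te = as<double>(par["Te"]);
  p.dstrength = as<double>(par["distractor_strength"]);
  p.repcap = as<double>(par["repeated_capture"]);  // <= 0 means off
  p.cv = as<double>(par["duration_cv"]);
  p.refresh_on = as<bool>(par["refresh_enabled"]);
  return p;
}

// lexicon in engine form; memoranda values live on the first dsize units
struct Lex {
  int n_mem = 0, n_types = 0, dsize = 0;
  std::vector<double> memv;                 // n_mem x dsize, row-major
  std::vector<std::vector<int>> sh;         // per type: shared units (< dsize)
  std::vector<std::vector<double>> shval;   // per type: values on shared units
};

inline double draw_dur(double mean, const Params& p) {
  if (mean <= 0) return 0.0;
  double v = mean + p.cv * mean * norm_rand();
  return v < 0.01 ? 0.01 : v;
}
inline double draw_rate(const Params& p) {
  double r = p.R + p.s * norm_rand();
  return r < 0.1 ? 0.1 : r;
}

// first k elements of a Fisher-Yates shuffle of 0..n-1
void sample_k(int n, int k, std::vector<int>& buf, std::vector<int>& out) {
  buf.resize(n);
  for (int i = 0; i < n; ++i) buf[i] = i;
  out.resize(k);
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(buf[i], buf[j]);
    out[i] = buf[i];
  }
}

void gen_lex(Lex& lex, int n_mem, int dsize, int n_types, double mdo,
             double mdd, std::vector<int>& buf, std::vector<int>& idx) {
  lex.n_mem = n_mem;
  lex.dsize = dsize;
  lex.n_types = n_types;
  lex.memv.resize((size_t)n_mem * dsize);
  for (double& v : lex.memv) v = unif_rand();
  std::vector<double> ref(dsize, 0.0);
  for (int m = 0; m < n_mem; ++m)
    for (int u = 0; u < dsize; ++u) ref[u] += lex.memv[(size_t)m * dsize + u];
  for (int u = 0; u < dsize; ++u) ref[u] /= n_mem;

  int k = (int)std::lround(mdo * dsize);
  lex.sh.assign(n_types, {});
  lex.shval.assign(n_types, {});
  for (int tpe = 0; tpe < n_types; ++tpe) {
    sample_k(dsize, k, buf, idx);
    lex.sh[tpe] = idx;
    lex.shval[tpe].resize(k);
    for (int i = 0; i < k; ++i) {
      // distractor values live on the same [0, 1] feature scale as memoranda
      double v = ref[idx[i]] + mdd * norm_rand();
      lex.shval[tpe][i] = v < 0 ? 0 : (v > 1 ? 1 : v);
    }
    for (int i = 0; i < dsize - k; ++i)
      unif_rand();  // non-overlapping units, outside the domain
  }
}

// scratch buffers reused across runs of a case
struct Work {
  std::vector<double> W;        // n_rows x n_pos_units
  std::vector<double> trow;     // per row: time weights were last materialised
  std::vector<char> active;
  std::vector<double> wmv;      // L x dsize working-memory copies (memoranda)
  std::vector<double> act;      // per-row activations at retrieval
  std::vector<int> buf, idx, list_items, token_type;
};

struct Trial {
  const Lex& lex;
  const Params& p;
  const std::vector<std::vector<int>>& pos;
  int npu;                      // total position units
  int L, n_rows, n_active;
  double t;
  Work& w;

  Trial(const Lex& lex_, const Params& p_,
        const std::vector<std::vector<int>>& pos_, int npu_, int L_, Work& w_)
      : lex(lex_), p(p_), pos(pos_), npu(npu_), L(L_),
        n_rows(L_ + lex_.n_types), n_active(0), t(0.0), w(w_) {
    w.W.assign((size_t)n_rows * npu, 0.0);
    w.trow.assign(n_rows, 0.0);
    w.active.assign(n_rows, 0);
    w.act.resize(n_rows);
    w.wmv.resize((size_t)L * lex.dsize);
  }

  // decay a row's weights up to the current clock
  void materialise(int r) {
    if (p.D > 0 && t > w.trow[r]) {
      double f = std::exp(-p.D * (t - w.trow[r]));
      double* row = &w.W[(size_t)r * npu];
      for (int u = 0; u < npu; ++u) row[u] *= f;
    }
    w.trow[r] = t;
  }

  // attend to row r at position pi for dur: everything decays, the attended
  // bindings then grow toward `strength`
  void encode_row(int r, int pi, double dur, double strength) {
    double rate = draw_rate(p);
    t += dur;
    materialise(r);
    double g = std::exp(-rate * dur);
    double* row = &w.W[(size_t)r * npu];
    for (int u : pos[pi]) row[u] = strength - (strength - row[u]) * g;
    if (!w.active[r]) { w.active[r] = 1; ++n_active; }
  }

  // winner row by noisy activation; -1 = omission
  int retrieve(int pi) {
    double best = -HUGE_VAL, best_act = 0.0;
    int win = -1;
    for (int r = 0; r < n_rows; ++r) {
      if (!w.active[r]) continue;
      double a = 0.0;
      const double* row = &w.W[(size_t)r * npu];
      for (int u : pos[pi]) a += row[u];
      if (p.D > 0 && t > w.trow[r]) a *= std::exp(-p.D * (t - w.trow[r]));
      double noisy = p.sigma > 0 ? a + p.sigma * norm_rand() : a;
      if (noisy > best) { best = noisy; win = r; best_act = a; }
    }
    int m_zero = lex.n_mem + lex.n_types - n_active;
    if (m_zero > 0 && p.sigma > 0) {
      // max of m_zero iid N(0, sigma) via inverse CDF of the maximum
      double u = unif_rand();
      double z = p.sigma * R::qnorm(std::pow(u, 1.0 / m_zero), 0.0, 1.0, 1, 0);
      if (z > best) return -1;  // a zero-activation candidate wins: omission
    }
    if (win < 0 || best_act < p.theta) return -1;
    return win;
  }

  // closest stable engram to the wm copy of list row lr; restoration and
  // recall output map memoranda representations onto memoranda engrams
  int identify(int lr) {
    const double* v = &w.wmv[(size_t)lr * lex.dsize];
    double best = HUGE_VAL;
    int win = -1;
    for (int m = 0; m < lex.n_mem; ++m) {
      const double* e = &lex.memv[(size_t)m * lex.dsize];
      double d = 0.0;
      for (int u = 0; u < lex.dsize; ++u) {
        double x = v[u] - e[u];
        d += x * x;
      }
      if (d < best) { best = d; win = m; }
    }
    return win;
  }

  // halfway-averaging of a list row's wm copy toward an engram
  void average_toward(int lr, int target) {
    double* v = &w.wmv[(size_t)lr * lex.dsize];
    if (target < lex.n_mem) {
      const double* e = &lex.memv[(size_t)target * lex.dsize];
      for (int u = 0; u < lex.dsize; ++u) v[u] = 0.5 * (v[u] + e[u]);
    } else {
      int tpe = target - lex.n_mem;
      int k = (int)lex.sh[tpe].size();
      for (int i = 0; i < k; ++i) {
        int u = lex.sh[tpe][i];
        v[u] = 0.5 * (v[u] + lex.shval[tpe][i]);
      }
    }
  }

  void free_time(double budget, int n_enc) {
    if (budget <= 0) return;
    if (!p.refresh_on || n_enc == 0) { t += budget; return; }
    double used = 0.0;
    int pi = 0;  // pointer resets to position 1 at each slot
    for (;;) {
      double step = draw_dur(p.Tr, p);
      if (used + step > budget) break;
      int win = retrieve(pi);
      if (win < 0) {
        t += step;  // nothing retrievable; time still passes
      } else {
        encode_row(win, pi, step, 1.0);  // reactivation
        if (win < L) average_toward(win, identify(win));  // restoration
      }
      used += step;
      pi = (pi + 1) % n_enc;
    }
    t += budget - used;
  }

  // returns the number of in-position correct recalls
  int run(int nd, double dac, double ft, bool hod_identical,
          int* recalled /* nullable, length L, 0 = omission, else 1-based */) {
    const std::vector<int>& items = w.list_items;   // L memoranda indices
    const std::vector<int>& toktype = w.token_type; // nd*L type indices
    bool reduced = hod_identical && p.repcap > 0;
    int token = 0;
    for (int i = 0; i < L; ++i) {
      // list row i holds memorandum items[i]; wm copy starts as the engram
      std::copy(&lex.memv[(size_t)items[i] * lex.dsize],
                &lex.memv[(size_t)items[i] * lex.dsize] + lex.dsize,
                &w.wmv[(size_t)i * lex.dsize]);
      encode_row(i, i, draw_dur(p.Te, p), 1.0);
      free_time(ft, i + 1);
      for (int d = 0; d < nd; ++d, ++token) {
        int tpe = toktype[token];
        double mean_cap = (reduced && d > 0) ? p.repcap : dac;
        encode_row(L + tpe, i, draw_dur(mean_cap, p), p.dstrength);
        // interference hits the last-presented memorandum
        double* v = &w.wmv[(size_t)i * lex.dsize];
        int k = (int)lex.sh[tpe].size();
        for (int s = 0; s < k; ++s) {
          int u = lex.sh[tpe][s];
          v[u] = 0.5 * (v[u] + lex.shval[tpe][s]);
        }
        free_time(ft, i + 1);
      }
    }
    int n_correct = 0;
    for (int pi = 0; pi < L; ++pi) {
      int win = retrieve(pi);
      int out = 0;
      if (win >= 0) {
        if (win < L) {
          int id = identify(win);
          if (id == items[pi]) ++n_correct;
          out = id + 1;
        } else {
          out = lex.n_mem + (win - L) + 1;  // distractor intrusion
        }
      }
      if (recalled) recalled[pi] = out;
      t += draw_dur(1.0 / p.R, p);  // decay continues during recall
    }
    return n_correct;
  }
};

std::vector<std::vector<int>> read_positions(const List& pos_sets) {
  std::vector<std::vector<int>> out(pos_sets.size());
  for (int i = 0; i < pos_sets.size(); ++i) {
    IntegerVector s = pos_sets[i];
    out[i].assign(s.begin(), s.end());
    for (int& u : out[i]) --u;  // to 0-based
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
NumericVector engine_run_case(int n_runs, int list_length, int nd, double dac,
                              double ft, double mdo, double mdd,
                              bool hod_identical, List par, List pos_sets,
                              int n_pos_units, int n_memoranda,
                              int domain_size) {
  Params p = read_params(par);
  std::vector<std::vector<int>> pos = read_positions(pos_sets);
  int L = list_length;
  int n_types = nd == 0 ? 0 : (hod_identical ? 1 : nd * L);
  NumericVector out(n_runs);
  Lex lex;
  Work w;
  w.token_type.resize((size_t)nd * L);
  for (int tok = 0; tok < nd * L; ++tok)
    w.token_type[tok] = hod_identical ? 0 : tok;
  for (int run = 0; run < n_runs; ++run) {
    gen_lex(lex, n_memoranda, domain_size, n_types, mdo, mdd, w.buf, w.idx);
    sample_k(n_memoranda, L, w.buf, w.list_items);
    Trial tr(lex, p, pos, n_pos_units, L, w);
    out[run] = tr.run(nd, dac, ft, hod_identical, nullptr) / (double)L;
  }
  return out;
}

// Single trial on an explicit lexicon and list (used to cross-check the
// compiled path against the R implementation).
// [[Rcpp::export]]
List engine_run_trial(int list_length, int nd, double dac, double ft,
                      bool hod_identical, List par, List pos_sets,
                      int n_pos_units, NumericMatrix values,
                      LogicalMatrix mask, LogicalVector is_distractor,
                      int domain_size, IntegerVector list_items,
                      IntegerVector token_type) {
  Params p = read_params(par);
  std::vector<std::vector<int>> pos = read_positions(pos_sets);
  int n_items = values.nrow();
  int n_mem = 0;
  for (int i = 0; i < n_items; ++i) if (!is_distractor[i]) ++n_mem;
  Lex lex;
  lex.n_mem = n_mem;
  lex.dsize = domain_size;
  lex.n_types = n_items - n_mem;
  lex.memv.resize((size_t)n_mem * domain_size);
  for (int m = 0; m < n_mem; ++m)
    for (int u = 0; u < domain_size; ++u)
      lex.memv[(size_t)m * domain_size + u] = values(m, u);
  lex.sh.assign(lex.n_types, {});
  lex.shval.assign(lex.n_types, {});
  for (int tpe = 0; tpe < lex.n_types; ++tpe) {
    int i = n_mem + tpe;
    for (int u = 0; u < values.ncol(); ++u) {
      if (!mask(i, u)) continue;
      if (u < domain_size) {
        lex.sh[tpe].push_back(u);
        lex.shval[tpe].push_back(values(i, u));
      }
    }
  }
  Work w;
  w.list_items.assign(list_items.begin(), list_items.end());
  for (int& x : w.list_items) --x;
  w.token_type.assign(token_type.begin(), token_type.end());
  for (int& x : w.token_type) x -= n_mem + 1;  // lexicon index -> type index
  Trial tr(lex, p, pos, n_pos_units, list_length, w);
  std::vector<int> recalled(list_length);
  int n_correct = tr.run(nd, dac, ft, hod_identical, recalled.data());
  IntegerVector rec(recalled.begin(), recalled.end());
  return List::create(_["recalled"] = rec, _["n_correct"] = n_correct,
                      _["clock"] = tr.t);
}
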