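#include <Rcpp.h>
#include <deque>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// round-half-to-even division of exact 64-bit integers
static inline int64_t div_half_even(int64_t n, int64_t d) {
  if (d < 0) { n = -n; d = -d; }
  int64_t q = n / d;            // truncates toward zero
  int64_t r = n - q * d;
  if (r < 0) { q -= 1; r += d; } // floor division
  if (2 * r > d || (2 * r == d && (q & 1))) q += 1;
  return q;
}

static inline int16_t sat16(int64_t v, int *sat_count) {
  if (v > 32767)  { ++*sat_count; return 32767; }
  if (v < -32768) { ++*sat_count; return -32768; }
  return (int16_t)v;
}

static const int64_t ACC_MAX = 2147483647LL;

static inline void check_acc(int64_t acc, const char *what) {
  if (acc > ACC_MAX || acc < -ACC_MAX - 1)
    stop("%s overflowed the 32-bit signed range", what);
}

// ---------------------------------------------------------------------------
// stateful DSP kernels shared by the stream entry points and the pipeline
// executive

struct FilterKernel {
  std::vector<int> b, a;
  std::vector<int64_t> xs, ys;   // newest first
  int sat = 0;
  FilterKernel(const IntegerVector &b_, const IntegerVector &a_)
      : b(b_.begin(), b_.end()), a(a_.begin(), a_.end()),
        xs(b_.size(), 0), ys(a_.size(), 0) {}
  int16_t assess(int64_t x) {
    for (size_t k = xs.size() - 1; k > 0; --k) xs[k] = xs[k - 1];
    xs[0] = x;
    int64_t acc = 0;
    for (size_t k = 0; k < b.size(); ++k) acc += (int64_t)b[k] * xs[k];
    for (size_t k = 1; k < a.size(); ++k) acc -= (int64_t)a[k] * ys[k - 1];
    check_acc(acc, "filter accumulator");
    int16_t y = sat16(div_half_even(acc, a[0]), &sat);
    for (size_t k = ys.size() - 1; k > 0; --k) ys[k] = ys[k - 1];
    ys[0] = y;
    return y;
  }
};

struct PolyKernel {
  std::vector<int> h;
  std::vector<int64_t> xs;
  int D;
  long long n_in = 0;
  int sat = 0;
  PolyKernel(const IntegerVector &h_, int D_)
      : h(h_.begin(), h_.end()), xs(h_.size(), 0), D(D_) {}
  // returns true and sets *out when an output is emitted
  bool assess(int64_t x, int16_t *out) {
    for (size_t k = xs.size() - 1; k > 0; --k) xs[k] = xs[k - 1];
    xs[0] = x;
    ++n_in;
    if ((n_in - 1) % D != 0) return false;
    int64_t acc = 0;
    for (size_t k = 0; k < h.size(); ++k) acc += (int64_t)h[k] * xs[k];
    check_acc(acc, "polyphase accumulator");
    *out = sat16(div_half_even(acc, 32768), &sat);
    return true;
  }
};

struct BlockKernel {
  int L, H, fill = 0;
  bool emit_samples;   // true: emit the whole window; false: emit its energy
  std::vector<double> buf;
  BlockKernel(int L_, int H_, bool emit_samples_)
      : L(L_), H(H_), emit_samples(emit_samples_), buf(L_, 0.0) {}
  bool add(double x, std::vector<double> *out) {
    buf[fill++] = x;
    if (fill < L) return false;
    if (emit_samples) {
      out->assign(buf.begin(), buf.end());
    } else {
      double e = 0;
      for (int i = 0; i < L; ++i) e += buf[i] * buf[i];
      if (e > (double)ACC_MAX) stop("block energy overflowed the 32-bit range");
      out->assign(1, e);
    }
    // advance: keep newest L - H
    for (int i = 0; i < L - H; ++i) buf[i] = buf[i + H];
    fill = L - H;
    return true;
  }
};

struct GoertzelKernel {
  double c;     // cos(w0)
  int N, iter = 0;
  double s1 = 0, s2 = 0;
  GoertzelKernel(double c_, int N_) : c(c_), N(N_) {}
  void step(double x) {
    double s = x + 2 * c * s1 - s2;
    s2 = s1;
    s1 = s;
  }
  bool add(double x, double *out) {
    step(x);
    if (++iter < N) return false;
    step(0.0);
    *out = s1 * s1 + s2 * s2 - 2 * s1 * s2 * c;
    s1 = s2 = 0;
    iter = 0;
    return true;
  }
};

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_q15_filter(IntegerVector x, IntegerVector b, IntegerVector a) {
  FilterKernel f(b, a);
  IntegerVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = f.assess(x[i]);
  if (f.sat > 0)
    warning("q15_filter: %d output(s) saturated to 16-bit range", f.sat);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_q15_polyphase(IntegerVector x, IntegerVector h, int D) {
  PolyKernel pk(h, D);
  std::vector<int> out;
  out.reserve(x.size() / D + 1);
  int16_t y;
  for (R_xlen_t i = 0; i < x.size(); ++i)
    if (pk.assess(x[i], &y)) out.push_back(y);
  if (pk.sat > 0)
    warning("q15_polyphase: %d output(s) saturated to 16-bit range", pk.sat);
  return wrap(out);
}

// [[Rcpp::export]]
NumericVector cpp_block_energy(IntegerVector x, int L, int H) {
  BlockKernel bk(L, H, false);
  std::vector<double> res, tmp;
  for (R_xlen_t i = 0; i < x.size(); ++i)
    if (bk.add(x[i], &tmp)) res.push_back(tmp[0]);
  return wrap(res);
}

// ---------------------------------------------------------------------------
// pipeline executive for one channel: a bounded hardware queue fed one code
// per acquisition tick, then a task-manager round in which each stage
// drains its input queue in declared order. Deterministic by construction.
//
// stages: list of lists with $type in {"filter","polyphase","block_energy",
// "block_emit","goertzel"}, stage parameters, and $capacity of the stage's
// *output* queue (the final stage's output is unbounded).
// drain_whole: drain the entire input queue per round (default task-manager
// behaviour) or serve a single sample per stage per round (stress mode).

// [[Rcpp::export]]
List cpp_sim_chain(IntegerVector codes, int lq, List stages, bool drain_whole) {
  int ns = stages.size();
  std::vector<std::deque<double>> queues(ns + 1); // queues[i] feeds stage i
  std::vector<int> capacity(ns + 1);
  capacity[0] = lq;
  std::vector<double> pushed(ns + 1, 0), popped(ns + 1, 0), overflow(ns + 1, 0);
  std::vector<double> invocations(ns, 0);

  std::vector<FilterKernel> fks;
  std::vector<PolyKernel> pks;
  std::vector<BlockKernel> bks;
  std::vector<GoertzelKernel> gks;
  std::vector<int> kind(ns), slot(ns);
  for (int i = 0; i < ns; ++i) {
    List st = stages[i];
    std::string type = as<std::string>(st["type"]);
    capacity[i + 1] = st.containsElementNamed("capacity")
                          ? as<int>(st["capacity"]) : INT32_MAX;
    if (type == "filter") {
      kind[i] = 0; slot[i] = fks.size();
      fks.emplace_back(as<IntegerVector>(st["b"]), as<IntegerVector>(st["a"]));
    } else if (type == "polyphase") {
      kind[i] = 1; slot[i] = pks.size();
      pks.emplace_back(as<IntegerVector>(st["h"]), as<int>(st["D"]));
    } else if (type == "block_energy" || type == "block_emit") {
      kind[i] = 2; slot[i] = bks.size();
      bks.emplace_back(as<int>(st["L"]), as<int>(st["H"]),
                       type == "block_emit");
    } else if (type == "goertzel") {
      kind[i] = 3; slot[i] = gks.size();
      gks.emplace_back(as<double>(st["cos_w0"]), as<int>(st["N"]));
    } else {
      stop("unknown stage type '%s'", type.c_str());
    }
  }

  std::vector<double> out;
  std::vector<double> emitted; // scratch for multi-sample stage outputs

  // stage i emits v: final stage writes to the unbounded output stream,
  // inner stages push onto the next bounded queue (reject-newest on full)
  auto emit = [&](int i, double v) {
    if (i == ns - 1) {
      out.push_back(v);
      return;
    }
    int qi = i + 1;
    if ((int)queues[qi].size() >= capacity[qi]) {
      overflow[qi] += 1;
      return;
    }
    queues[qi].push_back(v);
    pushed[qi] += 1;
  };

  for (R_xlen_t t = 0; t < codes.size(); ++t) {
    // acquisition tick: hardware layer pushes one code
    if ((int)queues[0].size() >= lq) {
      overflow[0] += 1;
    } else {
      queues[0].push_back(codes[t]);
      pushed[0] += 1;
    }
    // task-manager round
    for (int i = 0; i < ns; ++i) {
      size_t budget = drain_whole ? queues[i].size()
                                  : (queues[i].empty() ? 0 : 1);
      for (size_t n = 0; n < budget; ++n) {
        double v = queues[i].front();
        queues[i].pop_front();
        popped[i] += 1;
        invocations[i] += 1;
        switch (kind[i]) {
        case 0:
          emit(i, fks[slot[i]].assess((int64_t)v));
          break;
        case 1: {
          int16_t y;
          if (pks[slot[i]].assess((int64_t)v, &y)) emit(i, y);
          break;
        }
        case 2:
          if (bks[slot[i]].add(v, &emitted))
            for (double e : emitted) emit(i, e);
          break;
        case 3: {
          double p;
          if (gks[slot[i]].add(v, &p)) emit(i, p);
          break;
        }
        }
      }
    }
  }

  int sat = 0;
  for (auto &f : fks) sat += f.sat;
  for (auto &p : pks) sat += p.sat;

  std::vector<double> residual(ns + 1);
  for (int i = 0; i <= ns; ++i) residual[i] = (double)queues[i].size();

  return List::create(
      _["out"] = wrap(out),
      _["pushed"] = wrap(pushed),
      _["popped"] = wrap(popped),
      _["overflow"] = wrap(overflow),
      _["residual"] = wrap(residual),
      _["invocations"] = wrap(invocations),
      _["saturations"] = sat);
}
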