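// Event-driven graphical constructions for the voter model and the contact
// process started from a single occupied site at the origin.
//
// Events are materialized lazily: only Poisson arrows with an endpoint in the
// currently occupied set are generated (two thinned streams for the voter
// model; source-occupied arrows plus per-site recovery marks for the contact
// process).  This is exact for the set-valued trajectory and sufficient for
// every dual walk / ancestral query anchored at an occupied space-time point,
// because ancestral paths never leave the occupied set.
//
// All randomness comes from R's global generator (unif_rand / exp_rand), so
// set.seed() on the R side makes every run reproducible.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// occupied set with O(1) membership, insert, delete and uniform sampling;
// sites are packed into 64-bit keys (62/d bits per signed coordinate)
struct SiteSet {
  int d, B;
  long long off, mask;
  std::vector<long long> elems;
  std::unordered_map<long long, int> pos;

  explicit SiteSet(int d_) : d(d_) {
    B = 62 / d;
    off = 1LL << (B - 1);
    mask = (1LL << B) - 1;
  }
  long long pack(const int* x) const {
    long long key = 0;
    for (int j = 0; j < d; j++) {
      long long c = (long long)x[j] + off;
      if (c < 0 || c > mask)
        stop("site coordinate exceeds the packable range for this dimension");
      key = (key << B) | c;
    }
    return key;
  }
  void unpack(long long key, int* x) const {
    for (int j = d - 1; j >= 0; j--) {
      x[j] = (int)((key & mask) - off);
      key >>= B;
    }
  }
  bool contains(long long k) const { return pos.find(k) != pos.end(); }
  void insert_new(long long k) {
    pos[k] = (int)elems.size();
    elems.push_back(k);
  }
  void erase(long long k) {
    std::unordered_map<long long, int>::iterator it = pos.find(k);
    int i = it->second;
    long long last = elems.back();
    elems[i] = last;
    pos[last] = i;
    elems.pop_back();
    pos.erase(it);
  }
  int size() const { return (int)elems.size(); }
  long long random_elem() const {
    int i = (int)(unif_rand() * elems.size());
    if (i >= (int)elems.size()) i = (int)elems.size() - 1;
    return elems[i];
  }
};

int sample_offset(const NumericVector& cum) {
  double u = unif_rand();
  int lo = 0, hi = cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (u <= cum[mid]) hi = mid; else lo = mid + 1;
  }
  return lo;
}

double norm2_site(const int* x, int d) {
  double s = 0;
  for (int j = 0; j < d; j++) s += (double)x[j] * x[j];
  return s;
}

// status codes
const int ST_ALIVE = 0, ST_EXTINCT = 1, ST_EXITED = 2, ST_CENSORED = 3;

struct RunResult {
  int status;
  double surv_time, exit_time, stop_time, max_r2;
  long long n_events;
  std::vector<double> jump_times;
  std::vector<int> jump_sizes;
  std::vector<double> arrows;      // rows: time, target..., source...
  std::vector<double> recoveries;  // rows: time, site...
  std::vector<long long> final_set;
};

// one voter realization; arrows applied with the rule xi(target) <- xi(source)
RunResult voter_run(const IntegerMatrix& offsets, const NumericVector& cum,
                    double t_max, double exit_r2, long long max_events,
                    int max_sites, bool record, bool store_jumps) {
  int d = offsets.ncol();
  SiteSet T(d);
  std::vector<int> origin(d, 0), xbuf(d), ybuf(d);
  T.insert_new(T.pack(&origin[0]));

  RunResult res;
  res.status = ST_ALIVE;
  res.surv_time = NA_REAL;
  res.exit_time = NA_REAL;
  res.max_r2 = 0.0;
  res.n_events = 0;
  double t = 0.0;

  while (true) {
    int sz = T.size();
    if (sz == 0) { res.status = ST_EXTINCT; break; }
    if (sz >= max_sites || res.n_events >= max_events) {
      res.status = ST_CENSORED;
      break;
    }
    double rate = 2.0 * sz;
    t += exp_rand() / rate;
    if (t > t_max) { res.status = ST_ALIVE; t = t_max; break; }
    res.n_events++;

    bool streamA = unif_rand() < 0.5;
    int oi = sample_offset(cum);
    long long xk, yk;
    if (streamA) {
      // arrow into an occupied target x from y = x + e (D symmetric)
      xk = T.random_elem();
      T.unpack(xk, &xbuf[0]);
      for (int j = 0; j < d; j++) ybuf[j] = xbuf[j] + offsets(oi, j);
      yk = T.pack(&ybuf[0]);
      bool y_occ = T.contains(yk);
      if (record) {
        res.arrows.push_back(t);
        for (int j = 0; j < d; j++) res.arrows.push_back(xbuf[j]);
        for (int j = 0; j < d; j++) res.arrows.push_back(ybuf[j]);
      }
      if (!y_occ) {
        T.erase(xk);  // target adopts the source's 0 opinion
        if (store_jumps) {
          res.jump_times.push_back(t);
          res.jump_sizes.push_back(T.size());
        }
      }
    } else {
      // arrow out of an occupied source y into x = y + e; both-occupied
      // duplicates of stream A are discarded (not real extra events)
      yk = T.random_elem();
      T.unpack(yk, &ybuf[0]);
      for (int j = 0; j < d; j++) xbuf[j] = ybuf[j] + offsets(oi, j);
      xk = T.pack(&xbuf[0]);
      if (!T.contains(xk)) {
        T.insert_new(xk);
        if (record) {
          res.arrows.push_back(t);
          for (int j = 0; j < d; j++) res.arrows.push_back(xbuf[j]);
          for (int j = 0; j < d; j++) res.arrows.push_back(ybuf[j]);
        }
        if (store_jumps) {
          res.jump_times.push_back(t);
          res.jump_sizes.push_back(T.size());
        }
        double r2 = norm2_site(&xbuf[0], d);
        if (r2 > res.max_r2) res.max_r2 = r2;
        if (exit_r2 >= 0 && r2 > exit_r2) {
          res.status = ST_EXITED;
          res.exit_time = t;
          break;
        }
      }
    }
  }
  if (res.status == ST_EXTINCT) res.surv_time = t;
  res.stop_time = t;
  res.final_set = T.elems;
  return res;
}

// one contact-process realization: recovery marks at rate 1 per infected
// site, infection arrows at rate lambda D(.) out of each infected site
RunResult contact_run(const IntegerMatrix& offsets, const NumericVector& cum,
                      double lambda, double t_max, double exit_r2,
                      long long max_events, int max_sites, bool record,
                      bool store_jumps) {
  int d = offsets.ncol();
  SiteSet T(d);
  std::vector<int> origin(d, 0), xbuf(d), ybuf(d);
  T.insert_new(T.pack(&origin[0]));

  RunResult res;
  res.status = ST_ALIVE;
  res.surv_time = NA_REAL;
  res.exit_time = NA_REAL;
  res.max_r2 = 0.0;
  res.n_events = 0;
  double t = 0.0;

  while (true) {
    int sz = T.size();
    if (sz == 0) { res.status = ST_EXTINCT; break; }
    if (sz >= max_sites || res.n_events >= max_events) {
      res.status = ST_CENSORED;
      break;
    }
    double rate = (1.0 + lambda) * sz;
    t += exp_rand() / rate;
    if (t > t_max) { res.status = ST_ALIVE; t = t_max; break; }
    res.n_events++;

    if (unif_rand() < 1.0 / (1.0 + lambda)) {
      // recovery mark at an infected site
      long long xk = T.random_elem();
      T.unpack(xk, &xbuf[0]);
      if (record) {
        res.recoveries.push_back(t);
        for (int j = 0; j < d; j++) res.recoveries.push_back(xbuf[j]);
      }
      T.erase(xk);
      if (store_jumps) {
        res.jump_times.push_back(t);
        res.jump_sizes.push_back(T.size());
      }
    } else {
      // infection arrow out of an infected source; arrows between infected
      // sites are kept in the record (they matter for ancestry)
      long long yk = T.random_elem();
      T.unpack(yk, &ybuf[0]);
      int oi = sample_offset(cum);
      for (int j = 0; j < d; j++) xbuf[j] = ybuf[j] + offsets(oi, j);
      long long xk = T.pack(&xbuf[0]);
      if (record) {
        res.arrows.push_back(t);
        for (int j = 0; j < d; j++) res.arrows.push_back(xbuf[j]);
        for (int j = 0; j < d; j++) res.arrows.push_back(ybuf[j]);
      }
      if (!T.contains(xk)) {
        T.insert_new(xk);
        if (store_jumps) {
          res.jump_times.push_back(t);
          res.jump_sizes.push_back(T.size());
        }
        double r2 = norm2_site(&xbuf[0], d);
        if (r2 > res.max_r2) res.max_r2 = r2;
        if (exit_r2 >= 0 && r2 > exit_r2) {
          res.status = ST_EXITED;
          res.exit_time = t;
          break;
        }
      }
    }
  }
  if (res.status == ST_EXTINCT) res.surv_time = t;
  res.stop_time = t;
  res.final_set = T.elems;
  return res;
}

IntegerMatrix unpack_set(const std::vector<long long>& keys, int d) {
  SiteSet tmp(d);
  IntegerMatrix out((int)keys.size(), d);
  std::vector<int> buf(d);
  for (int i = 0; i < (int)keys.size(); i++) {
    tmp.unpack(keys[i], &buf[0]);
    for (int j = 0; j < d; j++) out(i, j) = buf[j];
  }
  return out;
}

List wrap_run(const RunResult& r, int d) {
  NumericMatrix arrows(0, 1 + 2 * d), recov(0, 1 + d);
  if (!r.arrows.empty()) {
    int nc = 1 + 2 * d, nr = (int)r.arrows.size() / nc;
    arrows = NumericMatrix(nr, nc);
    for (int i = 0; i < nr; i++)
      for (int j = 0; j < nc; j++) arrows(i, j) = r.arrows[i * nc + j];
  }
  if (!r.recoveries.empty()) {
    int nc = 1 + d, nr = (int)r.recoveries.size() / nc;
    recov = NumericMatrix(nr, nc);
    for (int i = 0; i < nr; i++)
      for (int j = 0; j < nc; j++) recov(i, j) = r.recoveries[i * nc + j];
  }
  return List::create(
    _["status"] = r.status,
    _["survival_time"] = r.surv_time,
    _["exit_time"] = r.exit_time,
    _["stop_time"] = r.stop_time,
    _["max_radius2"] = r.max_r2,
    _["n_events"] = (double)r.n_events,
    _["jump_times"] = NumericVector(r.jump_times.begin(), r.jump_times.end()),
    _["jump_sizes"] = IntegerVector(r.jump_sizes.begin(), r.jump_sizes.end()),
    _["final_set"] = unpack_set(r.final_set, d),
    _["arrows"] = arrows,
    _["recoveries"] = recov);
}

double moment_sum(const std::vector<long long>& keys, int d, double p) {
  SiteSet tmp(d);
  std::vector<int> buf(d);
  double s = 0;
  for (size_t i = 0; i < keys.size(); i++) {
    tmp.unpack(keys[i], &buf[0]);
    s += std::pow(norm2_site(&buf[0], d), p / 2.0);
  }
  return s;
}

}  // namespace

// [[Rcpp::export]]
List cpp_particle_run(std::string model, IntegerMatrix offsets,
                      NumericVector cum, double lambda, double t_max,
                      double exit_radius, double max_events, int max_sites,
                      bool record, bool store_jumps) {
  double r2 = exit_radius >= 0 ? exit_radius * exit_radius : -1.0;
  RunResult r;
  if (model == "voter")
    r = voter_run(offsets, cum, t_max, r2, (long long)max_events, max_sites,
                  record, store_jumps);
  else if (model == "contact")
    r = contact_run(offsets, cum, lambda, t_max, r2, (long long)max_events,
                    max_sites, record, store_jumps);
  else
    stop("unknown model");
  return wrap_run(r, offsets.ncol());
}

// batch runner for Monte-Carlo experiments: per replicate returns status,
// survival time, |T_{t_max}|, max squared radius, and (optionally, p >= 0)
// sum_{x in T_{t_max}} |x|^p
// [[Rcpp::export]]
List cpp_particle_batch(std::string model, IntegerMatrix offsets,
                        NumericVector cum, double lambda, double t_max,
                        double exit_radius, double max_events, int max_sites,
                        int reps, double moment_p) {
  double r2 = exit_radius >= 0 ? exit_radius * exit_radius : -1.0;
  IntegerVector status(reps), fsize(reps);
  NumericVector surv(reps), maxr2(reps), mom(reps), nev(reps);
  bool is_voter = (model == "voter");
  if (!is_voter && model != "contact") stop("unknown model");
  for (int i = 0; i < reps; i++) {
    RunResult r = is_voter
      ? voter_run(offsets, cum, t_max, r2, (long long)max_events, max_sites,
                  false, false)
      : contact_run(offsets, cum, lambda, t_max, r2, (long long)max_events,
                    max_sites, false, false);
    status[i] = r.status;
    surv[i] = r.surv_time;
    fsize[i] = (int)r.final_set.size();
    maxr2[i] = r.max_r2;
    nev[i] = (double)r.n_events;
    mom[i] = moment_p >= 0 ? moment_sum(r.final_set, offsets.ncol(), moment_p)
                           : NA_REAL;
    if (i % 4096 == 0) checkUserInterrupt();
  }
  return List::create(
    _["status"] = status, _["survival_time"] = surv, _["final_size"] = fsize,
    _["max_radius2"] = maxr2, _["moment_sum"] = mom, _["n_events"] = nev);
}

// max Euclidean displacement between breakpoints of a step path whose
// (sorted, increasing) breakpoint times differ by at most each window
// [[Rcpp::export]]
NumericVector cpp_window_max_disp(NumericVector times, NumericMatrix pos,
                                  NumericVector windows) {
  int k = times.size(), d = pos.ncol(), nw = windows.size();
  NumericVector out(nw);
  for (int w = 0; w < nw; w++) {
    double win = windows[w], best = 0.0;
    for (int a = 0; a < k; a++) {
      for (int b = a + 1; b < k && times[b] - times[a] <= win; b++) {
        double s = 0;
        for (int j = 0; j < d; j++) {
          double diff = pos(b, j) - pos(a, j);
          s += diff * diff;
        }
        if (s > best) best = s;
      }
    }
    out[w] = std::sqrt(best);
  }
  return out;
}
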