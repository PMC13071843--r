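#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Work-hours calendar. Calendar time is measured in days with t = 0 at
// Monday 00:00; the first `dpw` days of each 7-day week are workdays, and the
// daily service window starts at `s` (fraction of a day) and lasts `h` days.
// The "work clock" accumulates only in-window time, so queueing can be run in
// a clock where servers are continuously available.
struct WorkCal {
  int dpw;
  double s, h;
};

static double cal2work(double t, const WorkCal &c) {
  if (t <= 0) return 0.0;
  double week = std::floor(t / 7.0);
  double rem = t - 7.0 * week;
  double w = week * c.dpw * c.h;
  for (int i = 0; i < c.dpw; ++i) {
    double x = rem - (i + c.s);
    if (x < 0) x = 0;
    if (x > c.h) x = c.h;
    w += x;
  }
  return w;
}

static double work2cal(double w, const WorkCal &c) {
  if (w <= 0) return c.s;  // first window opens Monday at s
  double wk = c.dpw * c.h;
  double week = std::floor(w / wk + 1e-9);
  double rem = w - week * wk;
  if (rem < 0) rem = 0;
  // a work instant on a window boundary belongs to the NEXT window opening
  // (it is where an out-of-hours arrival is first serviceable)
  int day = (int)std::floor(rem / c.h + 1e-9);
  double within = rem - day * c.h;
  if (within < 0) within = 0;
  if (day >= c.dpw) {
    week += 1.0;
    day = 0;
    within = 0;
  }
  return 7.0 * week + day + c.s + within;
}

// [[Rcpp::export]]
NumericVector cal_to_work_cpp(NumericVector t, int dpw, double s, double h) {
  WorkCal c{dpw, s, h};
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = NumericVector::is_na(t[i]) ? NA_REAL : cal2work(t[i], c);
  return out;
}

// [[Rcpp::export]]
NumericVector work_to_cal_cpp(NumericVector w, int dpw, double s, double h) {
  WorkCal c{dpw, s, h};
  int n = w.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = NumericVector::is_na(w[i]) ? NA_REAL : work2cal(w[i], c);
  return out;
}

// One queue job. stage: 0 = first eConsult review, 1 = re-review after a
// more-information request, 2 = in-person assessment. Jobs are FIFO by
// (arrival work-time, spawn sequence); there is no priority between stages
// (first-come, first-served for both strategies).
struct Job {
  double t;
  long seq;
  int pat;
  int stage;
};
struct JobLater {
  bool operator()(const Job &a, const Job &b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.seq > b.seq;
  }
};

// Multi-server FIFO queue with dynamically spawned follow-up jobs.
// All times are on the work clock. Per referred patient i:
//  - consent[i] == 0: one in-person job arrives at arr[i];
//  - consent[i] == 1: a review job arrives at arr[i]; on completion,
//    out1[i]: 0 approve (done), 1 more information (re-review arrives
//    `delay_days` calendar days after completion), 2 in-person visit (job
//    arrives at completion). Re-review out2[i]: 0 approve, 2 in-person.
// Returns an n x 7 matrix: r1_start, r1_end, r2_start, r2_end, ip_join,
// ip_start, ip_end (work clock; NA where the stage does not occur).
// [[Rcpp::export]]
NumericMatrix queue_sim_cpp(NumericVector arr, IntegerVector consent,
                            IntegerVector out1, IntegerVector out2,
                            NumericVector svc_ip, NumericVector svc_r1,
                            NumericVector svc_r2, double delay_days,
                            int n_servers, int dpw, double s, double h) {
  WorkCal cal{dpw, s, h};
  int n = arr.size();
  NumericMatrix res(n, 7);
  std::fill(res.begin(), res.end(), NA_REAL);

  std::priority_queue<Job, std::vector<Job>, JobLater> arrivals;
  std::queue<Job> fifo;
  std::priority_queue<double, std::vector<double>, std::greater<double> > srv;
  for (int k = 0; k < n_servers; ++k) srv.push(0.0);

  long seq = 0;
  for (int i = 0; i < n; ++i) {
    if (consent[i] == 1) {
      arrivals.push(Job{arr[i], seq++, i, 0});
    } else {
      arrivals.push(Job{arr[i], seq++, i, 2});
      res(i, 4) = arr[i];  // ip_join
    }
  }

  while (!arrivals.empty() || !fifo.empty()) {
    double tf = srv.top();
    while (!arrivals.empty() && arrivals.top().t <= tf) {
      fifo.push(arrivals.top());
      arrivals.pop();
    }
    Job j{};
    double start;
    if (!fifo.empty()) {
      j = fifo.front();
      fifo.pop();
      start = tf;
    } else {
      j = arrivals.top();
      arrivals.pop();
      start = j.t;
    }
    srv.pop();
    double svc = (j.stage == 0) ? svc_r1[j.pat]
                                : (j.stage == 1) ? svc_r2[j.pat] : svc_ip[j.pat];
    double end = start + svc;
    srv.push(end);

    int i = j.pat;
    if (j.stage == 0) {
      res(i, 0) = start;
      res(i, 1) = end;
      if (out1[i] == 1) {
        double t2 = cal2work(work2cal(end, cal) + delay_days, cal);
        arrivals.push(Job{t2, seq++, i, 1});
      } else if (out1[i] == 2) {
        res(i, 4) = end;
        arrivals.push(Job{end, seq++, i, 2});
      }
    } else if (j.stage == 1) {
      res(i, 2) = start;
      res(i, 3) = end;
      if (out2[i] == 2) {
        res(i, 4) = end;
        arrivals.push(Job{end, seq++, i, 2});
      }
    } else {
      res(i, 5) = start;
      res(i, 6) = end;
    }
  }
  return res;
}
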