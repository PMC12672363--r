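#include <Rcpp.h>
using namespace Rcpp;

// Per-sample trial controller. Position is in mm, inward positive, already
// median-filtered. All timing is done in integer sample indices; event times
// are reported on the sample grid (i / fs). Semantics:
//  - a trial starts once the lever has stayed inside the +/- detection band
//    continuously for no_move_hold seconds (hold_n + 1 still samples, so the
//    elapsed still time is >= no_move_hold) and any pending ITI has elapsed;
//  - threshold crossings are rising-edge comparisons against the previous
//    sample; the reward window opens at the detection crossing of the ongoing
//    press and a reward crossing counts only if strictly inside the window;
//  - reward delivery occurs reward_delay after the reward crossing and ends
//    the trial; otherwise the trial times out at trial_timeout;
//  - an incomplete trailing trial (trace ends mid-trial) is discarded.
// [[Rcpp::export]]
List run_task_engine(NumericVector p, double fs,
                     double detection_threshold, double press_threshold,
                     double reward_threshold,
                     double no_move_hold, double reward_window,
                     double reward_delay, double trial_timeout, double iti,
                     int shift_trial, double shift_fraction) {
  const int n = p.size();
  const int hold_n = (int)std::lround(no_move_hold * fs);
  const int window_n = (int)std::lround(reward_window * fs);
  const int delay_n = (int)std::lround(reward_delay * fs);
  const int timeout_n = (int)std::lround(trial_timeout * fs);
  const int iti_n = (int)std::lround(iti * fs);

  std::vector<int> tr_index;
  std::vector<double> tr_start, tr_end, tr_reward;
  std::vector<int> tr_rewarded;

  std::vector<double> ev_time;
  std::vector<int> ev_kind;   // 1 detection_cross, 2 press_cross, 3 reward_cross, 4 reward_delivery
  std::vector<int> ev_trial;

  // events of the current (possibly incomplete) trial are buffered
  std::vector<double> cur_ev_time;
  std::vector<int> cur_ev_kind;

  int state = 0;              // 0 hold/armed, 1 in trial, 2 iti
  int still_run = 0;
  int trial_idx = 0;          // 1-based once started
  int start_i = 0, timeout_i = 0, iti_end_i = 0;
  bool window_open = false, committed = false;
  int ws_i = 0, delivery_i = 0;
  double rthr = reward_threshold;

  for (int i = 0; i < n; ++i) {
    if (state == 1) {
      if (committed && i >= delivery_i) {
        double tdel = (double)delivery_i / fs;
        cur_ev_time.push_back(tdel); cur_ev_kind.push_back(4);
        tr_index.push_back(trial_idx);
        tr_start.push_back((double)start_i / fs);
        tr_end.push_back(tdel);
        tr_reward.push_back(tdel);
        tr_rewarded.push_back(1);
        for (size_t k = 0; k < cur_ev_time.size(); ++k) {
          ev_time.push_back(cur_ev_time[k]);
          ev_kind.push_back(cur_ev_kind[k]);
          ev_trial.push_back(trial_idx);
        }
        cur_ev_time.clear(); cur_ev_kind.clear();
        state = 2; iti_end_i = delivery_i + iti_n;
        still_run = (std::fabs(p[i]) < detection_threshold) ? 1 : 0;
        continue;
      }
      if (!committed && i >= timeout_i) {
        tr_index.push_back(trial_idx);
        tr_start.push_back((double)start_i / fs);
        tr_end.push_back((double)timeout_i / fs);
        tr_reward.push_back(NA_REAL);
        tr_rewarded.push_back(0);
        for (size_t k = 0; k < cur_ev_time.size(); ++k) {
          ev_time.push_back(cur_ev_time[k]);
          ev_kind.push_back(cur_ev_kind[k]);
          ev_trial.push_back(trial_idx);
        }
        cur_ev_time.clear(); cur_ev_kind.clear();
        state = 2; iti_end_i = timeout_i + iti_n;
        still_run = (std::fabs(p[i]) < detection_threshold) ? 1 : 0;
        continue;
      }
      double prev = p[i - 1], cur = p[i];
      double t = (double)i / fs;
      if (prev < detection_threshold && cur >= detection_threshold) {
        cur_ev_time.push_back(t); cur_ev_kind.push_back(1);
        if (!window_open) { window_open = true; ws_i = i; }
      }
      if (prev < press_threshold && cur >= press_threshold) {
        cur_ev_time.push_back(t); cur_ev_kind.push_back(2);
      }
      if (prev < rthr && cur >= rthr) {
        if (window_open && (i - ws_i) < window_n && !committed) {
          cur_ev_time.push_back(t); cur_ev_kind.push_back(3);
          committed = true;
          delivery_i = i + delay_n;
        }
      }
      if (window_open && cur < detection_threshold) window_open = false;
      continue;
    }
    // non-trial states: track stillness
    if (std::fabs(p[i]) < detection_threshold) ++still_run; else still_run = 0;
    if (state == 2) {
      if (i < iti_end_i) continue;
      state = 0;
    }
    if (still_run >= hold_n + 1) {
      ++trial_idx;
      start_i = i;
      timeout_i = i + timeout_n;
      state = 1;
      window_open = false; committed = false;
      rthr = reward_threshold;
      if (shift_trial > 0 && trial_idx >= shift_trial)
        rthr = reward_threshold * (1.0 + shift_fraction);
    }
  }

  return List::create(
    _["trial_index"] = wrap(tr_index),
    _["start_time"] = wrap(tr_start),
    _["end_time"] = wrap(tr_end),
    _["reward_time"] = wrap(tr_reward),
    _["rewarded"] = wrap(tr_rewarded),
    _["event_time"] = wrap(ev_time),
    _["event_kind"] = wrap(ev_kind),
    _["event_trial"] = wrap(ev_trial));
}
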