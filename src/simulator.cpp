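// Agent-based simulation of the perceptual-crossing world: two avatars on a
// 1-D ring, each additionally feeling a private static object and the
// partner's shadow (the partner's avatar displaced by a fixed offset).
// Haptic contact is binary; avatar-avatar contact is symmetric, shadow and
// static contacts are one-sided by construction.
//
// Controller: while scanning, move at scan_speed with persistent direction
// and random reversals. On a contact onset while scanning, the agent opens a
// probing episode against the touched object: with probability alpha an
// engaged (M) episode of tau * probe_window steps, otherwise a passive (L)
// episode of probe_window steps. Passive probing is sensing in passing (the
// agent keeps moving); engaged probing oscillates about the stimulation
// site, reversing whenever contact with the probed object is lost and
// staying within engage_range of the anchor.

#include <Rcpp.h>
#include <random>
using namespace Rcpp;

namespace {

struct Config {
  double ring_length, object_width, shadow_offset;
  double scan_speed, engage_speed, turn_prob, engage_range, contact_frac;
  double speed_jitter;
  int probe_window, tau, trial_steps, onset_min;
  double static_a, static_b;
};

// All positions stay in [0, L) and single-step displacements are far below
// L, so wrapping needs no general modulo.
inline double wrap(double x, double L) {
  while (x >= L) x -= L;
  while (x < 0) x += L;
  return x;
}

inline double circ_dist(double a, double b, double L) {
  double d = std::fabs(a - b);  // a, b in [0, L)
  return std::min(d, L - d);
}

// signed offset of x from ref, in (-L/2, L/2]
inline double circ_offset(double x, double ref, double L) {
  double d = x - ref;  // in (-L, L)
  if (d > L / 2) d -= L;
  if (d <= -L / 2) d += L;
  return d;
}

struct Episode {
  int agent, start, object, strategy, onsets, contact, window;
  bool detected, truncated;
};

struct Agent {
  double pos;
  int dir;              // +1 / -1
  int mode;             // 0 scan, 1 probe (L), 2 engage (M)
  double alpha;
  double anchor;
  int window_left, window_nominal;
  int ep_object, ep_onsets, ep_contact, ep_start;
  bool ep_prev, loss_flag;
  bool prev_contact[3];
  std::mt19937_64 rng;

  double unif() {
    return std::uniform_real_distribution<double>(0.0, 1.0)(rng);
  }
  double norm() {
    return std::normal_distribution<double>(0.0, 1.0)(rng);
  }
};

const int OBJ_STATIC = 0, OBJ_AVATAR = 1, OBJ_SHADOW = 2;

void finalize_episode(Agent& ag, const Config& cfg, bool truncated,
                      std::vector<Episode>& log) {
  Episode ep;
  ep.agent = 0;  // filled by caller
  ep.start = ag.ep_start;
  ep.object = ag.ep_object;
  ep.strategy = (ag.mode == 2) ? 1 : 0;
  ep.onsets = ag.ep_onsets;
  ep.contact = ag.ep_contact;
  ep.window = ag.window_nominal;
  ep.truncated = truncated;
  ep.detected = !truncated &&
    ag.ep_object == OBJ_AVATAR &&
    ag.ep_onsets >= cfg.onset_min &&
    ag.ep_contact >= cfg.contact_frac * ag.window_nominal;
  log.push_back(ep);
  ag.mode = 0;
  ag.ep_object = -1;
}

}  // namespace

// [[Rcpp::export(name = ".sim_trial_cpp")]]
List sim_trial_cpp(List cfg_in, double alpha_a, double alpha_b,
                   int seed, int cond, int trial, bool keep_trace) {
  Config cfg;
  cfg.ring_length   = as<double>(cfg_in["ring_length"]);
  cfg.object_width  = as<double>(cfg_in["object_width"]);
  cfg.shadow_offset = as<double>(cfg_in["shadow_offset"]);
  cfg.scan_speed    = as<double>(cfg_in["scan_speed"]);
  cfg.engage_speed  = as<double>(cfg_in["engage_speed"]);
  cfg.turn_prob     = as<double>(cfg_in["turn_prob"]);
  cfg.engage_range  = as<double>(cfg_in["engage_range"]);
  cfg.speed_jitter  = as<double>(cfg_in["speed_jitter"]);
  cfg.contact_frac  = as<double>(cfg_in["contact_frac"]);
  cfg.probe_window  = as<int>(cfg_in["probe_window"]);
  cfg.tau           = as<int>(cfg_in["tau"]);
  cfg.trial_steps   = as<int>(cfg_in["trial_steps"]);
  cfg.onset_min     = as<int>(cfg_in["onset_min"]);
  cfg.static_a      = as<double>(cfg_in["static_pos"]);
  cfg.static_b      = as<double>(cfg_in["static_pos_b"]);

  Agent ag[2];
  for (int k = 0; k < 2; ++k) {
    std::seed_seq ss{seed, cond, trial, k + 1};
    ag[k].rng.seed(ss);
    ag[k].pos = ag[k].unif() * cfg.ring_length;
    ag[k].dir = (ag[k].unif() < 0.5) ? 1 : -1;
    ag[k].mode = 0;
    ag[k].ep_object = -1;
    ag[k].loss_flag = false;
    ag[k].ep_prev = false;
    for (int i = 0; i < 3; ++i) ag[k].prev_contact[i] = false;
  }
  ag[0].alpha = alpha_a;
  ag[1].alpha = alpha_b;

  std::vector<Episode> log[2];

  NumericMatrix trace;
  if (keep_trace) trace = NumericMatrix(cfg.trial_steps, 7);

  for (int t = 1; t <= cfg.trial_steps; ++t) {
    // 1. velocities
    for (int k = 0; k < 2; ++k) {
      Agent& a = ag[k];
      if (a.mode == 2) {
        double off = circ_offset(a.pos, a.anchor, cfg.ring_length);
        if (off > cfg.engage_range && a.dir > 0) a.dir = -1;
        else if (off < -cfg.engage_range && a.dir < 0) a.dir = 1;
        else if (a.loss_flag) a.dir = -a.dir;
      } else {
        if (a.unif() < cfg.turn_prob) a.dir = -a.dir;
      }
      a.loss_flag = false;
    }

    // 2. move (small speed noise so that co-directional contacts drift
    //    slowly in and out of touch instead of freezing)
    for (int k = 0; k < 2; ++k) {
      double speed = (ag[k].mode == 2) ? cfg.engage_speed : cfg.scan_speed;
      double v = ag[k].dir * speed + cfg.speed_jitter * ag[k].norm();
      ag[k].pos = wrap(ag[k].pos + v, cfg.ring_length);
    }

    // 3. contacts: objects felt by k are (own static, partner avatar,
    //    partner shadow = partner avatar + offset)
    bool contact[2][3];
    double objpos[2][3];
    for (int k = 0; k < 2; ++k) {
      int o = 1 - k;
      objpos[k][OBJ_STATIC] = (k == 0) ? cfg.static_a : cfg.static_b;
      objpos[k][OBJ_AVATAR] = ag[o].pos;
      objpos[k][OBJ_SHADOW] =
        wrap(ag[o].pos + cfg.shadow_offset, cfg.ring_length);
      for (int i = 0; i < 3; ++i) {
        contact[k][i] =
          circ_dist(ag[k].pos, objpos[k][i], cfg.ring_length) <
          cfg.object_width;
      }
    }

    // 4. episode bookkeeping and mode transitions
    for (int k = 0; k < 2; ++k) {
      Agent& a = ag[k];
      if (a.mode != 0) {
        bool now = contact[k][a.ep_object];
        if (now && !a.ep_prev) a.ep_onsets++;
        if (now) a.ep_contact++;
        a.loss_flag = (a.ep_prev && !now);
        a.ep_prev = now;
        if (--a.window_left == 0) {
          int mode_was = a.mode;
          (void)mode_was;
          finalize_episode(a, cfg, false, log[k]);
        }
      } else {
        // onset detection while scanning
        int chosen = -1;
        double best = 1e300;
        for (int i = 0; i < 3; ++i) {
          if (contact[k][i] && !a.prev_contact[i]) {
            double d = circ_dist(a.pos, objpos[k][i], cfg.ring_length);
            if (d < best - 1e-12) { best = d; chosen = i; }
          }
        }
        if (chosen >= 0) {
          bool engage = a.unif() < a.alpha;
          a.mode = engage ? 2 : 1;
          a.window_nominal =
            engage ? cfg.tau * cfg.probe_window : cfg.probe_window;
          a.window_left = a.window_nominal;
          a.anchor = a.pos;
          a.ep_object = chosen;
          a.ep_onsets = 1;
          a.ep_contact = 1;
          a.ep_start = t;
          a.ep_prev = true;
          a.loss_flag = false;
        }
      }
      for (int i = 0; i < 3; ++i) a.prev_contact[i] = contact[k][i];
    }

    if (keep_trace) {
      trace(t - 1, 0) = t;
      trace(t - 1, 1) = ag[0].pos;
      trace(t - 1, 2) = ag[1].pos;
      int ca = contact[0][0] * 1 + contact[0][1] * 2 + contact[0][2] * 4;
      int cb = contact[1][0] * 1 + contact[1][1] * 2 + contact[1][2] * 4;
      trace(t - 1, 3) = ca;
      trace(t - 1, 4) = cb;
      trace(t - 1, 5) = ag[0].mode;
      trace(t - 1, 6) = ag[1].mode;
    }
  }

  // truncated episodes at trial end are logged but flagged
  for (int k = 0; k < 2; ++k) {
    if (ag[k].mode != 0) finalize_episode(ag[k], cfg, true, log[k]);
  }

  int n = log[0].size() + log[1].size();
  IntegerVector agent(n), start(n), object(n), strategy(n), onsets(n),
      contact_steps(n), window(n);
  LogicalVector detected(n), truncated(n);
  int r = 0;
  for (int k = 0; k < 2; ++k) {
    for (size_t e = 0; e < log[k].size(); ++e, ++r) {
      const Episode& ep = log[k][e];
      agent[r] = k + 1;
      start[r] = ep.start;
      object[r] = ep.object + 1;  // 1 static, 2 avatar, 3 shadow
      strategy[r] = ep.strategy;
      onsets[r] = ep.onsets;
      contact_steps[r] = ep.contact;
      window[r] = ep.window;
      detected[r] = ep.detected;
      truncated[r] = ep.truncated;
    }
  }
  List episodes = List::create(
      _["agent"] = agent, _["start"] = start, _["object"] = object,
      _["strategy"] = strategy, _["onsets"] = onsets,
      _["contact_steps"] = contact_steps, _["window"] = window,
      _["detected"] = detected, _["truncated"] = truncated);

  if (keep_trace) {
    return List::create(_["episodes"] = episodes, _["trace"] = trace);
  }
  return List::create(_["episodes"] = episodes);
}

// Pooled detection counts for one strategy pair over n_trials trials:
// returns (detections, avatar encounters) for agent 1 plus totals of all
// episodes, avoiding per-trial R round trips.
// [[Rcpp::export(name = ".sim_counts_cpp")]]
IntegerVector sim_counts_cpp(List cfg_in, double alpha_a, double alpha_b,
                             int seed, int cond, int n_trials) {
  long det = 0, enc = 0, episodes_all = 0, avatar_frac_num = 0;
  for (int trial = 1; trial <= n_trials; ++trial) {
    List res = sim_trial_cpp(cfg_in, alpha_a, alpha_b, seed, cond, trial,
                             false);
    List ep = res["episodes"];
    IntegerVector agent = ep["agent"], object = ep["object"];
    LogicalVector detected = ep["detected"], truncated = ep["truncated"];
    for (int i = 0; i < agent.size(); ++i) {
      if (truncated[i]) continue;
      if (agent[i] != 1) continue;
      episodes_all++;
      if (object[i] == 2) {
        avatar_frac_num++;
        enc++;
        if (detected[i]) det++;
      }
    }
  }
  return IntegerVector::create(
      _["detections"] = (int)det, _["encounters"] = (int)enc,
      _["episodes"] = (int)episodes_all,
      _["avatar_episodes"] = (int)avatar_frac_num);
}
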