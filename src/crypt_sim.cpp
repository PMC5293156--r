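#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Cell class codes shared with the R layer (R/lattice.R keeps the mapping):
//   cls : 0 = SC, 1 = niche, 2 = progenitor, 3 = differentiated
//   fate: 0 = uncommitted, 1 = secretory, 2 = absorptive
// Grid convention: row 0 is the crypt base (SC row), rows increase upward.
// Hexagonal adjacency uses "odd-row right-shifted" offset coordinates on a
// cylinder (columns wrap): every interior site has 6 neighbours.
// Division targets are the three higher sites (columns c-1, c, c+1 of the
// row above); the progeny's column is then pushed strictly vertically.

struct Cfg {
  int R, C, n_ta, cz, diff_start, mode; // mode: 0 early, 1 late, 2 cz
  int cz_continuous;                    // 1: maintained, 0: entry+exit, 2: entry only
  int sched_exp;                        // 1: exponential clocks, 0: cycle-time clocks
  int track_ta;                         // fresh clone id per TA entrant
  double p_sec, period_mean, period_cv, meanlog, sdlog;
  double sync, mixing, gdf, gmf, shp, p_swap;
};

static inline int wrapc(int c, int C) { return ((c % C) + C) % C; }

static inline int runif_int(int k) {
  int i = (int)(unif_rand() * k);
  return i >= k ? k - 1 : i;
}

// fills nb with up to 6 (row, col) pairs, returns count
static int hex_nb(const Cfg& cfg, int r, int c, int nb[6][2]) {
  int n = 0;
  nb[n][0] = r; nb[n][1] = wrapc(c - 1, cfg.C); ++n;
  nb[n][0] = r; nb[n][1] = wrapc(c + 1, cfg.C); ++n;
  int off = (r % 2 == 0) ? -1 : 0; // even rows: diagonals at c-1, c; odd: c, c+1
  for (int dr = -1; dr <= 1; dr += 2) {
    int rr = r + dr;
    if (rr < 0 || rr >= cfg.R) continue;
    nb[n][0] = rr; nb[n][1] = wrapc(c + off, cfg.C); ++n;
    nb[n][0] = rr; nb[n][1] = wrapc(c + off + 1, cfg.C); ++n;
  }
  return n;
}

struct Engine {
  Cfg cfg;
  IntegerMatrix cls, fate, clone_id, delta;
  NumericMatrix period, nextt;
  double t;

  // counters
  double n_div = 0, n_ext = 0, n_ta_entries = 0, n_diff_entries = 0,
         n_sc_div = 0, n_sc_horiz = 0, n_mix_swaps = 0,
         n_ext_sec = 0, n_ext_abs = 0;
  std::vector<double> departures; // per row
  // differentiated-compartment entrant log
  std::vector<double> ent_time;
  std::vector<int> ent_fate, ent_clone;
  // committed outflow from the commitment zone (cz mode)
  std::vector<double> czx_time;
  std::vector<int> czx_fate, czx_moved; // moved=1: pushed out, 0: progeny born above
  // optional event log (divisions)
  bool record_events;
  std::vector<double> ev_time;
  std::vector<int> ev_row, ev_col, ev_trow, ev_tcol, ev_clone, ev_horiz;

  bool check_inv;
  int ta_clone_counter = 0;
  int czq_counter = 0; // diagnostic quota commitment (cz_continuous == 3)
  int n_violations = 0;
  IntegerVector row0_cls0; // initial base-row composition

  Engine(List state, List cfgl, bool rec_ev, bool chk)
      : cls(as<IntegerMatrix>(state["cls"])),
        fate(as<IntegerMatrix>(state["fate"])),
        clone_id(as<IntegerMatrix>(state["clone_id"])),
        delta(as<IntegerMatrix>(state["delta"])),
        period(as<NumericMatrix>(state["period"])),
        nextt(as<NumericMatrix>(state["next_t"])),
        t(as<double>(state["time"])),
        record_events(rec_ev), check_inv(chk) {
    cfg.R = cls.nrow(); cfg.C = cls.ncol();
    cfg.n_ta = as<int>(cfgl["n_ta_rows"]);
    cfg.cz = as<int>(cfgl["cz_rows"]);
    cfg.diff_start = cfg.n_ta + 1;
    cfg.mode = as<int>(cfgl["mode"]);
    cfg.cz_continuous = as<int>(cfgl["cz_continuous"]);
    cfg.sched_exp = as<int>(cfgl["sched_exponential"]);
    cfg.track_ta = as<int>(cfgl["track_ta_clones"]);
    cfg.p_sec = as<double>(cfgl["p_secretory"]);
    cfg.period_mean = as<double>(cfgl["division_period"]);
    cfg.period_cv = as<double>(cfgl["period_cv"]);
    if (cfg.period_cv > 0) {
      cfg.sdlog = sqrt(log(1.0 + cfg.period_cv * cfg.period_cv));
      cfg.meanlog = log(cfg.period_mean) - 0.5 * cfg.sdlog * cfg.sdlog;
    } else { cfg.sdlog = 0; cfg.meanlog = 0; }
    cfg.sync = as<double>(cfgl["sync"]);
    cfg.mixing = as<double>(cfgl["mixing"]);
    cfg.gdf = as<double>(cfgl["goblet_division_factor"]);
    cfg.gmf = as<double>(cfgl["goblet_migration_factor"]);
    cfg.shp = as<double>(cfgl["sc_horizontal_prob"]);
    cfg.p_swap = cfg.mixing * cfg.gmf;
    if (cfg.p_swap > 1) cfg.p_swap = 1;
    departures.assign(cfg.R, 0.0);
    for (int i = 0; i < cfg.R * cfg.C; ++i)
      if (clone_id[i] >= ta_clone_counter) ta_clone_counter = clone_id[i] + 1;
    row0_cls0 = IntegerVector(cfg.C);
    for (int c = 0; c < cfg.C; ++c) row0_cls0[c] = cls(0, c);
  }

  double fresh_period() {
    if (cfg.period_cv <= 0) return cfg.period_mean;
    return R::rlnorm(cfg.meanlog, cfg.sdlog);
  }

  // TA progeny inherit their parent's realized period with probability
  // sync; stem-cell divisions always hand out fresh periods, so rate
  // synchronization is clonal rather than crypt-wide.
  double draw_period(double parent) {
    if (cfg.sync > 0 && unif_rand() < cfg.sync) return parent;
    return fresh_period();
  }

  double div_rate(int r, int c) const {
    int k = cls(r, c);
    if (k == 0) return 1.0 / period(r, c);
    if (k == 2) return (fate(r, c) == 1 ? cfg.gdf : 1.0) / period(r, c);
    return 0.0;
  }

  void schedule(int r, int c) {
    double rate = div_rate(r, c);
    if (!R_FINITE(rate) || rate <= 0) { nextt(r, c) = R_PosInf; return; }
    if (cfg.sched_exp) nextt(r, c) = t + exp_rand() / rate;
    else // one full cycle; tiny jitter breaks ties between synchronous kin
      nextt(r, c) = t + (1.0 / rate) * (1.0 + 1e-9 * unif_rand());
  }

  bool cz_has_secretory_neighbor(int r, int c) {
    int nb[6][2], n = hex_nb(cfg, r, c, nb);
    for (int i = 0; i < n; ++i) {
      int rr = nb[i][0], cc = nb[i][1];
      if (rr >= 1 && rr <= cfg.cz && fate(rr, cc) == 1) return true;
    }
    return false;
  }

  // entry of a commitment-zone resident: default-Delta unless inhibited
  void cz_commit(int r, int c) {
    if (!delta(r, c)) { set_fate(r, c, 2); return; }
    if (cfg.cz_continuous == 3) { // diagnostic: deterministic 1:4 quota
      set_fate(r, c, (czq_counter++ % 4 == 0) ? 1 : 2);
      return;
    }
    set_fate(r, c, cz_has_secretory_neighbor(r, c) ? 2 : 1);
  }

  void cz_exit_check(int r, int c) { // exit check wins over the entry fate
    if (fate(r, c) == 1 && cz_has_secretory_neighbor(r, c)) set_fate(r, c, 2);
  }

  // Maintained lateral inhibition: after every event, restore the stable
  // Delta pattern inside the zone. First pass demotes one of each adjacent
  // secretory pair created by cell movement; second pass re-promotes
  // Delta-capable cells whose inhibitor has left (default-Delta fate).
  // The fixed point is exclusion-consistent and maximal.
  void cz_relax() {
    for (int r = 1; r <= cfg.cz; ++r)
      for (int c = 0; c < cfg.C; ++c) {
        if (!delta(r, c)) { if (fate(r, c) != 2) set_fate(r, c, 2); continue; }
        if (fate(r, c) == 1 && cz_has_secretory_neighbor(r, c))
          set_fate(r, c, 2);
      }
    for (int r = 1; r <= cfg.cz; ++r)
      for (int c = 0; c < cfg.C; ++c)
        if (delta(r, c) && fate(r, c) != 1 && !cz_has_secretory_neighbor(r, c))
          set_fate(r, c, 1);
  }

  void set_fate(int r, int c, int f) {
    if (fate(r, c) == f) return;
    fate(r, c) = f;
    if (cls(r, c) == 2 && cfg.gdf != 1.0) schedule(r, c); // rate changed
  }

  void copy_cell(int rs, int cs, int rd, int cd) {
    cls(rd, cd) = cls(rs, cs); fate(rd, cd) = fate(rs, cs);
    clone_id(rd, cd) = clone_id(rs, cs); delta(rd, cd) = delta(rs, cs);
    period(rd, cd) = period(rs, cs); nextt(rd, cd) = nextt(rs, cs);
  }

  void swap_cells(int r1, int r2, int c) {
    int a;
    double d;
    a = cls(r1, c); cls(r1, c) = cls(r2, c); cls(r2, c) = a;
    a = fate(r1, c); fate(r1, c) = fate(r2, c); fate(r2, c) = a;
    a = clone_id(r1, c); clone_id(r1, c) = clone_id(r2, c); clone_id(r2, c) = a;
    a = delta(r1, c); delta(r1, c) = delta(r2, c); delta(r2, c) = a;
    d = period(r1, c); period(r1, c) = period(r2, c); period(r2, c) = d;
    d = nextt(r1, c); nextt(r1, c) = nextt(r2, c); nextt(r2, c) = d;
  }

  void log_diff_entry(int r, int c) {
    // a cell just arrived at diff_start: finalize it as post-mitotic
    if (cfg.mode == 1 && fate(r, c) == 0)
      fate(r, c) = unif_rand() < cfg.p_sec ? 1 : 2;
    cls(r, c) = 3;
    nextt(r, c) = R_PosInf;
    n_diff_entries += 1;
    ent_time.push_back(t);
    ent_fate.push_back(fate(r, c));
    ent_clone.push_back(clone_id(r, c));
  }

  // push column `col` upward starting at `from_row`; extrudes the top cell.
  // The caller then places the inserted cell at (from_row, col).
  void push_column(int col, int from_row) {
    int top = cfg.R - 1;
    n_ext += 1;
    departures[top] += 1;
    if (fate(top, col) == 1) n_ext_sec += 1; else n_ext_abs += 1;
    for (int r = top; r > from_row; --r) {
      copy_cell(r - 1, col, r, col);
      departures[r - 1] += 1;
    }
    // boundary processing for the cells that moved (bottom-up)
    for (int r = from_row + 1; r <= cfg.diff_start && r <= top; ++r) {
      if (cfg.mode == 2 && r == cfg.cz + 1) {
        if (cfg.cz_continuous == 0) cz_exit_check(r, col);
        czx_time.push_back(t); czx_fate.push_back(fate(r, col));
        czx_moved.push_back(1);
      }
      if (r == cfg.diff_start) log_diff_entry(r, col);
    }
    // dispersive migration: secretory cells let the absorptive cell that is
    // pushing past them slip by, so they lag behind (differentiated rows only)
    if (cfg.p_swap > 0) {
      for (int r = cfg.diff_start + 1; r <= top; ++r) {
        if (fate(r, col) == 1 && fate(r - 1, col) == 2 &&
            cls(r, col) == 3 && cls(r - 1, col) == 3 &&
            r - 1 > from_row && unif_rand() < cfg.p_swap) {
          swap_cells(r, r - 1, col);
          n_mix_swaps += 1;
        }
      }
    }
  }

  // place a newly arriving progenitor at the bottom TA row
  void place_ta_entrant(int col, int clone, int dlt, double per) {
    if (cfg.track_ta) clone = ta_clone_counter++;
    cls(1, col) = 2; clone_id(1, col) = clone; delta(1, col) = dlt;
    period(1, col) = per;
    n_ta_entries += 1;
    if (cfg.mode == 0) fate(1, col) = unif_rand() < cfg.p_sec ? 1 : 2;
    else if (cfg.mode == 1) fate(1, col) = 0;
    else cz_commit(1, col);
    schedule(1, col);
  }

  void divide(int r, int c) {
    n_div += 1;
    double child_per = cls(r, c) == 0 ? fresh_period()
                                      : draw_period(period(r, c));
    int trow = r + 1, tcol = wrapc(c + runif_int(3) - 1, cfg.C);
    bool horiz = false;

    if (cls(r, c) == 0) { // stem cell
      n_sc_div += 1;
      int cd = -1;
      if (unif_rand() < cfg.shp) { // nearest SC clockwise or counter-clockwise
        int step = unif_rand() < 0.5 ? 1 : -1;
        for (int k = 1; k < cfg.C; ++k) {
          int cc = wrapc(c + step * k, cfg.C);
          if (cls(0, cc) == 0) { cd = cc; break; }
        }
      }
      if (cd >= 0) { // horizontal: neutral-drift replacement of an adjacent SC
        horiz = true;
        n_sc_horiz += 1;
        trow = 1; tcol = cd;
        int d_clone = clone_id(0, cd), d_delta = delta(0, cd);
        double d_per = fresh_period(); // the displaced SC founds a TA clone
        departures[0] += 1;
        push_column(cd, 1);
        place_ta_entrant(cd, d_clone, d_delta, d_per); // the displaced SC
        // progeny takes the vacated SC site
        cls(0, cd) = 0; fate(0, cd) = 0;
        clone_id(0, cd) = clone_id(r, c); delta(0, cd) = delta(r, c);
        period(0, cd) = child_per;
        schedule(0, cd);
      } else { // upward division into the bottom TA row
        trow = 1;
        push_column(tcol, 1);
        place_ta_entrant(tcol, clone_id(r, c), delta(r, c), child_per);
      }
    } else { // progenitor: progeny replaces one of the three higher sites
      push_column(tcol, trow);
      cls(trow, tcol) = trow <= cfg.n_ta ? 2 : 3;
      clone_id(trow, tcol) = clone_id(r, c);
      delta(trow, tcol) = delta(r, c);
      period(trow, tcol) = child_per;
      if (cfg.mode == 1) fate(trow, tcol) = 0;
      else fate(trow, tcol) = fate(r, c); // clonal fate inheritance
      if (cfg.mode == 2 && trow <= cfg.cz) cz_commit(trow, tcol);
      if (cfg.mode == 2 && trow == cfg.cz + 1) {
        czx_time.push_back(t); czx_fate.push_back(fate(trow, tcol));
        czx_moved.push_back(0);
      }
      if (trow == cfg.diff_start) log_diff_entry(trow, tcol);
      else schedule(trow, tcol);
    }
    // the parent starts a new cycle: its next period follows the same
    // synchronization rule, so s = 0 gives uncorrelated successive cycles
    period(r, c) = cls(r, c) == 0 ? fresh_period() : draw_period(period(r, c));
    schedule(r, c);
    if (record_events) {
      ev_time.push_back(t); ev_row.push_back(r); ev_col.push_back(c);
      ev_trow.push_back(trow); ev_tcol.push_back(tcol);
      ev_clone.push_back(clone_id(r, c)); ev_horiz.push_back(horiz ? 1 : 0);
    }
  }

  void verify() {
    for (int c = 0; c < cfg.C; ++c)
      if (cls(0, c) != row0_cls0[c]) { ++n_violations; return; }
    for (int r = 0; r < cfg.R; ++r)
      for (int c = 0; c < cfg.C; ++c) {
        int k = cls(r, c);
        bool ok = (r == 0) ? (k == 0 || k == 1)
                : (r <= cfg.n_ta) ? (k == 2) : (k == 3);
        if (!ok) { ++n_violations; return; }
      }
    if (cfg.mode == 2 && cfg.cz_continuous == 1) { // exclusion inside the CZ
      int nb[6][2];
      for (int r = 1; r <= cfg.cz; ++r)
        for (int c = 0; c < cfg.C; ++c) {
          if (fate(r, c) != 1) continue;
          int n = hex_nb(cfg, r, c, nb);
          for (int i = 0; i < n; ++i) {
            int rr = nb[i][0], cc = nb[i][1];
            if (rr >= 1 && rr <= cfg.cz && fate(rr, cc) == 1) {
              ++n_violations; return;
            }
          }
        }
    }
    if (n_div != n_ext) ++n_violations;
  }

  List snapshot() {
    return List::create(_["time"] = t, _["cls"] = Rcpp::clone(cls),
                        _["fate"] = Rcpp::clone(fate),
                        _["clone_id"] = Rcpp::clone(clone_id));
  }
};

// [[Rcpp::export(name = ".crypt_engine")]]
List crypt_engine(List state, List cfgl, double duration,
                  NumericVector snapshot_times, bool record_events,
                  bool check_invariants) {
  Engine e(state, cfgl, record_events, check_invariants);
  double t_end = e.t + duration;
  int n_snap = snapshot_times.size(), snap_i = 0;
  List snaps(n_snap);

  while (true) {
    // next division event
    int br = -1, bc = -1;
    double tmin = R_PosInf;
    for (int c = 0; c < e.cfg.C; ++c)
      for (int r = 0; r <= e.cfg.n_ta; ++r)
        if (e.nextt(r, c) < tmin) { tmin = e.nextt(r, c); br = r; bc = c; }
    double t_next = (br >= 0) ? tmin : R_PosInf;
    while (snap_i < n_snap && snapshot_times[snap_i] <= std::min(t_next, t_end)) {
      e.t = snapshot_times[snap_i];
      snaps[snap_i] = e.snapshot();
      ++snap_i;
    }
    if (t_next > t_end) break;
    e.t = t_next;
    e.divide(br, bc);
    if (e.cfg.mode == 2 && e.cfg.cz_continuous == 1) e.cz_relax();
    if (check_invariants) e.verify();
  }
  e.t = t_end;

  List new_state = List::create(
      _["cls"] = e.cls, _["fate"] = e.fate, _["clone_id"] = e.clone_id,
      _["delta"] = e.delta, _["period"] = e.period, _["next_t"] = e.nextt,
      _["time"] = e.t);

  DataFrame entrants = DataFrame::create(
      _["time"] = wrap(e.ent_time), _["fate"] = wrap(e.ent_fate),
      _["clone_id"] = wrap(e.ent_clone));

  DataFrame cz_exits = DataFrame::create(
      _["time"] = wrap(e.czx_time), _["fate"] = wrap(e.czx_fate),
      _["moved"] = wrap(e.czx_moved));

  NumericVector counters = NumericVector::create(
      _["divisions"] = e.n_div, _["extrusions"] = e.n_ext,
      _["ta_entries"] = e.n_ta_entries, _["diff_entries"] = e.n_diff_entries,
      _["sc_divisions"] = e.n_sc_div, _["sc_horizontal"] = e.n_sc_horiz,
      _["mixing_swaps"] = e.n_mix_swaps,
      _["extruded_secretory"] = e.n_ext_sec,
      _["extruded_absorptive"] = e.n_ext_abs);

  List events = R_NilValue;
  if (record_events) {
    events = DataFrame::create(
        _["time"] = wrap(e.ev_time), _["row"] = wrap(e.ev_row),
        _["col"] = wrap(e.ev_col), _["target_row"] = wrap(e.ev_trow),
        _["target_col"] = wrap(e.ev_tcol), _["clone_id"] = wrap(e.ev_clone),
        _["horizontal"] = wrap(e.ev_horiz));
  }

  return List::create(
      _["state"] = new_state, _["counters"] = counters,
      _["entrants"] = entrants, _["cz_exits"] = cz_exits,
      _["departures"] = wrap(e.departures),
      _["obs_time"] = duration, _["snapshots"] = snaps,
      _["events"] = events, _["violations"] = e.n_violations);
}
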