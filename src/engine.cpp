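// Compiled simulation engine for the on-lattice MS lesion model.
//
// Layout and conventions (0-based internally, 1-based at the R surface):
//   - global columns 0..W-1: [0, Wb) blood, [Wb, Wb+Wp) PVS, rest parenchyma
//   - rows 0..H-1, periodic (wrap) in the row direction
//   - parenchyma arrays are column-major by parenchyma column:
//       idx = pc * H + r,  pc in [0, Wq), r in [0, H)
//   - blocks: bc = pc / B, br = r / B, b = bc * nby + br, nby = H / B
//   - directions: 0 = E (+col), 1 = W, 2 = N (-row), 3 = S (+row)
//
// All randomness is drawn from R's RNG (unif_rand), so set.seed() on the R
// side makes a run bit-reproducible. The draw order is fixed by the sub-step
// order below and by stable (insertion-order) agent iteration.
//
// Sub-step order within one step:
//   spawn -> move (primed, PVMs, unengaged reactivated) -> antigen
//   presentation -> engagement + degradation -> repair -> oligodendrocyte
//   status update -> death -> metrics.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Cell {
  int c, r;      // global column / row, 0-based
  bool engaged;  // reactivated T cells only
};

// Biased movement probabilities toward a target displaced by (dx, dy),
// dx > 0 east, dy > 0 south (+row). Probabilities are written to p[4] in
// direction order E, W, N, S. Negative entries (beta > 0.5) are clamped at
// zero and the vector renormalised. Axis-aligned convention: the favoured
// direction on a zero-displacement axis is east (dx == 0) / south (dy == 0)
// and keeps its unbiased 0.25.
void bias_probs(int dx, int dy, double s, double *p) {
  double ax = std::abs((double)dx), ay = std::abs((double)dy);
  double denom = ax + ay;
  p[0] = p[1] = p[2] = p[3] = 0.25;
  int fav_x = (dx < 0) ? 1 : 0;           // W : E
  int fav_y = (dy < 0) ? 2 : 3;           // N : S
  p[fav_x] += s * ax / denom;
  p[1 - fav_x] -= s / 2.0;
  p[fav_y] += s * ay / denom;
  p[fav_y == 2 ? 3 : 2] -= s / 2.0;
  double tot = 0.0;
  for (int i = 0; i < 4; ++i) {
    if (p[i] < 0.0) p[i] = 0.0;
    tot += p[i];
  }
  for (int i = 0; i < 4; ++i) p[i] /= tot;
}

// Nearest parenchyma site with myelin state >= 2, Euclidean metric, ties
// broken toward the lowest row then the lowest column. The cell sits at
// parenchyma-relative column px (negative while in blood/PVS) and row gr.
// elig holds per-parenchyma-column counts of eligible sites so empty
// columns are skipped in O(1). Returns false if nothing is eligible.
bool nearest_eligible(const std::vector<int> &st, const std::vector<int> &elig,
                      long total_elig, int Wq, int H, int px, int gr,
                      int &out_pc, int &out_r, double &out_d) {
  if (total_elig == 0) return false;
  long best = -1;
  int bpc = -1, brow = -1;
  for (int d = 0;; ++d) {
    long dx2 = (long)d * d;
    int cl = px - d, cr = px + d;
    bool cl_ok = (cl >= 0 && cl < Wq);
    bool cr_ok = (d > 0 && cr >= 0 && cr < Wq);
    if (!cl_ok && !cr_ok && cl < 0 && cr >= Wq) break;  // ran off both ends
    if (best >= 0 && dx2 > best) break;
    for (int which = 0; which < 2; ++which) {
      int pc = (which == 0) ? cl : cr;
      if ((which == 0 && !cl_ok) || (which == 1 && !cr_ok)) continue;
      if (elig[pc] == 0) continue;
      const int *col = &st[(size_t)pc * H];
      for (int e = 0;; ++e) {
        long d2 = dx2 + (long)e * e;
        if (best >= 0 && d2 > best) break;
        int r1 = gr - e, r2 = gr + e;
        if (r1 < 0 && r2 >= H) break;
        if (r1 >= 0 && col[r1] >= 2) {
          if (best < 0 || d2 < best ||
              (d2 == best && (r1 < brow || (r1 == brow && pc < bpc)))) {
            best = d2; bpc = pc; brow = r1;
          }
        }
        if (e > 0 && r2 < H && col[r2] >= 2) {
          if (best < 0 || d2 < best ||
              (d2 == best && (r2 < brow || (r2 == brow && pc < bpc)))) {
            best = d2; bpc = pc; brow = r2;
          }
        }
      }
    }
  }
  if (best < 0) return false;
  out_pc = bpc; out_r = brow; out_d = std::sqrt((double)best);
  return true;
}

int pick_dir(const double *p) {
  double u = unif_rand();
  double acc = 0.0;
  for (int i = 0; i < 3; ++i) {
    acc += p[i];
    if (u < acc) return i;
  }
  return 3;
}

class Sim {
public:
  // geometry / parameters
  int Wb, Wp, Wq, W, H, B, S, Wrep, n_steps, spd;
  double rhoR, rhoNR, rhod, bL, beta, k;
  int pvm_n;
  bool per_agent_damage;
  std::vector<double> relapse_on;
  double rel_dur;
  // live (treatable) parameters
  double live_bR;
  int live_om, live_la;
  // derived
  int NP, nbx, nby, NB;
  // fields
  std::vector<int> st, ctr, occ_stamp, deg_stamp;
  std::vector<int> elig;
  long total_elig;
  std::vector<int> sigma, status, dmg;  // per block; status 0/1/2
  long n_intact, n_state1;
  int n_myel, n_nonmyel, n_apop;
  // agents
  std::vector<Cell> primed, react, pvms;
  std::vector<int> pvm_stamp;  // over PVS sites, (c - Wb) * H + r
  bool bias_on;
  // per-block behaviour time (step counts)
  std::vector<int> beh_myel, beh_nonmyel, beh_apop;
  // per-step ledger
  int led_spawned, led_converted, led_pdeath, led_rdeath, led_premoved,
      led_rremoved;

  explicit Sim(const List &cfg) {
    Wb = as<int>(cfg["blood_width"]);
    Wp = as<int>(cfg["pvs_width"]);
    Wq = as<int>(cfg["parenchyma_width"]);
    W = as<int>(cfg["lattice_width"]);
    H = as<int>(cfg["lattice_height"]);
    B = as<int>(cfg["oligo_block"]);
    S = as<int>(cfg["n_myelin_states"]);
    Wrep = as<int>(cfg["repair_delay"]);
    n_steps = as<int>(cfg["n_steps"]);
    spd = as<int>(cfg["steps_per_day"]);
    rhoR = as<double>(cfg["rho_R"]);
    rhoNR = as<double>(cfg["rho_NR"]);
    rhod = as<double>(cfg["rho_d"]);
    live_bR = as<double>(cfg["b_R"]);
    bL = as<double>(cfg["b_L"]);
    beta = as<double>(cfg["beta"]);
    k = as<double>(cfg["k"]);
    live_om = as<int>(cfg["omega"]);
    live_la = as<int>(cfg["lambda_"]);
    pvm_n = as<int>(cfg["pvm_count"]);
    per_agent_damage = as<bool>(cfg["damage_per_agent"]);
    relapse_on = as<std::vector<double>>(cfg["relapse_onsets"]);
    rel_dur = as<double>(cfg["relapse_duration_days"]);

    NP = Wq * H;
    nby = H / B;
    nbx = Wq / B;
    NB = nbx * nby;
    st.assign(NP, S);
    ctr.assign(NP, 0);
    occ_stamp.assign(NP, -1);
    deg_stamp.assign(NP, -1);
    elig.assign(Wq, H);
    total_elig = NP;
    sigma.assign(NB, 0);
    status.assign(NB, 0);
    dmg.assign(NB, 0);
    n_intact = NP;
    n_state1 = 0;
    n_myel = NB;
    n_nonmyel = 0;
    n_apop = 0;
    pvm_stamp.assign((size_t)Wp * H, -1);
    bias_on = false;
    beh_myel.assign(NB, 0);
    beh_nonmyel.assign(NB, 0);
    beh_apop.assign(NB, 0);
    seed_pvms();
  }

  void seed_pvms() {
    // partial Fisher-Yates over the Wp * H PVS sites, without replacement
    int n_sites = Wp * H;
    std::vector<int> pool(n_sites);
    for (int i = 0; i < n_sites; ++i) pool[i] = i;
    pvms.reserve(pvm_n);
    for (int i = 0; i < pvm_n; ++i) {
      int j = i + (int)(unif_rand() * (n_sites - i));
      if (j >= n_sites) j = n_sites - 1;
      std::swap(pool[i], pool[j]);
      Cell m;
      m.c = Wb + pool[i] / H;
      m.r = pool[i] % H;
      m.engaged = false;
      pvms.push_back(m);
    }
  }

  bool relapse_active(int step0) const {
    double day = step0 / spd;
    for (double on : relapse_on) {
      if (day >= on && day < on + rel_dur) return true;
    }
    return false;
  }

  int block_of(int pc, int r) const { return (pc / B) * nby + r / B; }

  void spawn(bool relapse) {
    double rho = relapse ? rhoR : rhoNR;
    if (rho <= 0.0) return;
    int n_sites = Wb * H;
    for (int i = 0; i < n_sites; ++i) {
      if (unif_rand() < rho) {
        Cell a;
        a.c = i / H;
        a.r = i % H;
        a.engaged = false;
        primed.push_back(a);
        ++led_spawned;
      }
    }
  }

  // Resolve one movement event for a T cell (primed or reactivated) given
  // direction probabilities p. Returns false if the agent is removed at the
  // right (Dirichlet) boundary.
  bool move_tcell(Cell &a, const double *p) {
    int dir = pick_dir(p);
    switch (dir) {
      case 2: a.r = (a.r == 0) ? H - 1 : a.r - 1; return true;
      case 3: a.r = (a.r == H - 1) ? 0 : a.r + 1; return true;
      case 0:
        if (a.c == W - 1) return false;           // removed
        if (a.c == Wb - 1) {                      // blood -> PVS across BBB
          if (unif_rand() < live_bR) ++a.c;       // else stays (move consumed)
          return true;
        }
        ++a.c;
        return true;
      default:                                    // west
        if (a.c == 0) return true;                // left edge reflects
        if (a.c == Wb) {                          // PVS -> blood across BBB
          if (unif_rand() < bL) --a.c;
          return true;
        }
        --a.c;
        return true;
    }
  }

  void move_pvm(Cell &m) {
    static const double unif[4] = {0.25, 0.25, 0.25, 0.25};
    int dir = pick_dir(unif);
    switch (dir) {
      case 2: m.r = (m.r == 0) ? H - 1 : m.r - 1; break;
      case 3: m.r = (m.r == H - 1) ? 0 : m.r + 1; break;
      case 0: if (m.c < Wb + Wp - 1) ++m.c; break;  // reflected at PVS edge
      default: if (m.c > Wb) --m.c; break;
    }
  }

  void move_all() {
    static const double unif[4] = {0.25, 0.25, 0.25, 0.25};
    size_t keep = 0;
    for (size_t i = 0; i < primed.size(); ++i) {
      Cell a = primed[i];
      if (move_tcell(a, unif)) {
        primed[keep++] = a;
      } else {
        ++led_premoved;
      }
    }
    primed.resize(keep);
    for (auto &m : pvms) move_pvm(m);
    double p[4];
    keep = 0;
    for (size_t i = 0; i < react.size(); ++i) {
      Cell a = react[i];
      if (a.engaged) {  // engaged cells are stationary
        react[keep++] = a;
        continue;
      }
      const double *probs = unif;
      if (bias_on && total_elig > 0) {
        int pc, tr;
        double d;
        if (nearest_eligible(st, elig, total_elig, Wq, H, a.c - Wb - Wp, a.r,
                             pc, tr, d) &&
            d > 0.0) {  // own site eligible (post-restore): walk unbiased
          double s = beta * std::exp(-k * d);
          bias_probs(pc - (a.c - Wb - Wp), tr - a.r, s, p);
          probs = p;
        }
      }
      if (move_tcell(a, probs)) {
        react[keep++] = a;
      } else {
        ++led_rremoved;
      }
    }
    react.resize(keep);
  }

  void present_antigen(int step) {
    for (const auto &m : pvms) pvm_stamp[(size_t)(m.c - Wb) * H + m.r] = step;
    size_t keep = 0;
    for (size_t i = 0; i < primed.size(); ++i) {
      Cell a = primed[i];
      bool in_pvs = (a.c >= Wb && a.c < Wb + Wp);
      if (in_pvs && pvm_stamp[(size_t)(a.c - Wb) * H + a.r] == step) {
        a.engaged = false;
        react.push_back(a);  // reactivated at the site of presentation
        ++led_converted;
      } else {
        primed[keep++] = a;
      }
    }
    primed.resize(keep);
  }

  void engage_and_degrade(int step) {
    int boundary = Wb + Wp;
    for (auto &a : react) {
      if (a.c < boundary) continue;
      int pc = a.c - boundary;
      size_t idx = (size_t)pc * H + a.r;
      occ_stamp[idx] = step;
      if (!a.engaged && st[idx] >= 2) a.engaged = true;
    }
    for (auto &a : react) {
      if (!a.engaged) continue;
      int pc = a.c - boundary;
      size_t idx = (size_t)pc * H + a.r;
      if (!per_agent_damage) {
        if (deg_stamp[idx] == step) continue;
        deg_stamp[idx] = step;
      }
      if (st[idx] > 1) {
        int b = block_of(pc, a.r);
        if (st[idx] == S) {
          --n_intact;
          ++dmg[b];
          bias_on = true;  // latches at the first loss of full integrity
        }
        --st[idx];
        ctr[idx] = 0;
        if (st[idx] == 1) {
          ++sigma[b];
          ++n_state1;
          --elig[pc];
          --total_elig;
        }
      }
    }
  }

  void repair_step(int step) {
    if (n_intact == (long)NP) return;
    for (int b = 0; b < NB; ++b) {
      if (status[b] != 0 || dmg[b] == 0) continue;
      int pc0 = (b / nby) * B, r0 = (b % nby) * B;
      for (int pc = pc0; pc < pc0 + B; ++pc) {
        for (int r = r0; r < r0 + B; ++r) {
          size_t idx = (size_t)pc * H + r;
          if (st[idx] >= S) continue;
          if (occ_stamp[idx] == step) {
            ctr[idx] = 0;
            continue;
          }
          if (++ctr[idx] >= Wrep) {
            ctr[idx] = 0;
            if (st[idx] == 1) {
              --sigma[b];
              --n_state1;
              ++elig[pc];
              ++total_elig;
            }
            if (++st[idx] == S) {
              ++n_intact;
              --dmg[b];
            }
          }
        }
      }
    }
  }

  void zero_counters(int b) {
    int pc0 = (b / nby) * B, r0 = (b % nby) * B;
    for (int pc = pc0; pc < pc0 + B; ++pc)
      for (int r = r0; r < r0 + B; ++r) ctr[(size_t)pc * H + r] = 0;
  }

  void apoptose(int b) {
    int pc0 = (b / nby) * B, r0 = (b % nby) * B;
    for (int pc = pc0; pc < pc0 + B; ++pc) {
      for (int r = r0; r < r0 + B; ++r) {
        size_t idx = (size_t)pc * H + r;
        if (st[idx] > 1) {
          if (st[idx] == S) --n_intact;
          --elig[pc];
          --total_elig;
          st[idx] = 1;
        }
        ctr[idx] = 0;
      }
    }
    n_state1 += (long)B * B - sigma[b];
    sigma[b] = B * B;
    dmg[b] = B * B;
  }

  void update_status() {
    for (int b = 0; b < NB; ++b) {
      if (status[b] == 0 && sigma[b] >= live_om) {
        status[b] = 1;
        --n_myel;
        ++n_nonmyel;
        zero_counters(b);
      }
      if (status[b] == 1 && sigma[b] >= live_la) {
        status[b] = 2;
        --n_nonmyel;
        ++n_apop;
        apoptose(b);
      }
    }
  }

  void disengage_on_floor() {
    int boundary = Wb + Wp;
    for (auto &a : react) {
      if (!a.engaged) continue;
      size_t idx = (size_t)(a.c - boundary) * H + a.r;
      if (st[idx] == 1) a.engaged = false;
    }
  }

  void deaths() {
    if (rhod <= 0.0) return;
    size_t keep = 0;
    for (size_t i = 0; i < primed.size(); ++i) {
      if (unif_rand() < rhod) {
        ++led_pdeath;
      } else {
        primed[keep++] = primed[i];
      }
    }
    primed.resize(keep);
    keep = 0;
    for (size_t i = 0; i < react.size(); ++i) {
      if (unif_rand() < rhod) {
        ++led_rdeath;
      } else {
        react[keep++] = react[i];
      }
    }
    react.resize(keep);
  }

  void accumulate_behaviour() {
    for (int b = 0; b < NB; ++b) {
      switch (status[b]) {
        case 0: ++beh_myel[b]; break;
        case 1: ++beh_nonmyel[b]; break;
        default: ++beh_apop[b];
      }
    }
  }

  void restore_block(int b) {
    if (status[b] == 1) { --n_nonmyel; ++n_myel; }
    else if (status[b] == 2) { --n_apop; ++n_myel; }
    status[b] = 0;
    n_state1 -= sigma[b];
    sigma[b] = 0;
    int pc0 = (b / nby) * B, r0 = (b % nby) * B;
    for (int pc = pc0; pc < pc0 + B; ++pc) {
      for (int r = r0; r < r0 + B; ++r) {
        size_t idx = (size_t)pc * H + r;
        if (st[idx] < S) {
          if (st[idx] == 1) {
            ++elig[pc];
            ++total_elig;
          }
          st[idx] = S;
          ++n_intact;
        }
        ctr[idx] = 0;
      }
    }
    dmg[b] = 0;
  }

  void apply_plan(const List &plan) {
    if (plan.containsElementNamed("new_b_R") &&
        !Rf_isNull(plan["new_b_R"]))
      live_bR = as<double>(plan["new_b_R"]);
    bool has_om = plan.containsElementNamed("new_omega") &&
                  !Rf_isNull(plan["new_omega"]);
    bool has_la = plan.containsElementNamed("new_lambda") &&
                  !Rf_isNull(plan["new_lambda"]);
    if (has_om) live_om = as<int>(plan["new_omega"]);
    if (has_la) live_la = as<int>(plan["new_lambda"]);
    bool relatch = plan.containsElementNamed("relatch_nonmyelinating") &&
                   as<bool>(plan["relatch_nonmyelinating"]);
    if ((has_om || has_la) && !relatch) {
      // re-evaluate non-myelinating blocks against the new tolerance;
      // apoptosis stays absorbing
      for (int b = 0; b < NB; ++b) {
        if (status[b] == 1 && sigma[b] < live_om) {
          status[b] = 0;
          --n_nonmyel;
          ++n_myel;
          zero_counters(b);
        }
      }
    }
    if (plan.containsElementNamed("restore_fraction") &&
        !Rf_isNull(plan["restore_fraction"])) {
      double f = as<double>(plan["restore_fraction"]);
      bool impaired_only =
          plan.containsElementNamed("restore_scope") &&
          as<std::string>(plan["restore_scope"]) == "impaired";
      for (int b = 0; b < NB; ++b) {
        bool sel = unif_rand() < f || f >= 1.0;
        if (impaired_only && status[b] == 0) sel = false;
        if (sel) restore_block(b);
      }
      int boundary = Wb + Wp;
      for (auto &a : react) {  // engaged cells on restored sites let go
        if (!a.engaged) continue;
        size_t idx = (size_t)(a.c - boundary) * H + a.r;
        if (st[idx] == S) a.engaged = false;
      }
    }
  }

  void record(int step, bool relapse, double *row) const {
    int boundary = Wb + Wp;
    int n_par = 0;
    for (const auto &a : react)
      if (a.c >= boundary) ++n_par;
    row[0] = step;
    row[1] = relapse ? 1 : 0;
    row[2] = (double)primed.size();
    row[3] = (double)pvms.size();
    row[4] = (double)react.size();
    row[5] = n_par;
    row[6] = (double)n_intact / NP;
    row[7] = (double)(NP - n_intact - n_state1) / NP;
    row[8] = (double)n_state1 / NP;
    row[9] = (double)n_myel / NB;
    row[10] = (double)n_nonmyel / NB;
    row[11] = (double)n_apop / NB;
    row[12] = led_spawned;
    row[13] = led_converted;
    row[14] = led_pdeath;
    row[15] = led_rdeath;
    row[16] = led_premoved;
    row[17] = led_rremoved;
  }
};

}  // namespace

//' @name run_sim_cpp
//' @keywords internal
// [[Rcpp::export]]
List run_sim_cpp(List cfg, List plan, IntegerVector snapshot_steps) {
  Sim sim(cfg);
  const int n = sim.n_steps;
  const int ncol_metrics = 18;
  NumericMatrix metrics(n + 1, ncol_metrics);

  int plan_step = -1;
  if (plan.size() > 0 && plan.containsElementNamed("intervention_day") &&
      !Rf_isNull(plan["intervention_day"])) {
    plan_step = (int)std::lround(as<double>(plan["intervention_day"]) * sim.spd);
  }

  std::vector<bool> want_snap(n + 1, false);
  for (int i = 0; i < snapshot_steps.size(); ++i) {
    int s = snapshot_steps[i];
    if (s >= 0 && s <= n) want_snap[s] = true;
  }
  List snapshots;

  auto take_snapshot = [&](int s) {
    IntegerMatrix state(sim.H, sim.Wq);
    for (int pc = 0; pc < sim.Wq; ++pc)
      for (int r = 0; r < sim.H; ++r)
        state(r, pc) = sim.st[(size_t)pc * sim.H + r];
    IntegerMatrix stat(sim.nby, sim.nbx);
    for (int bc = 0; bc < sim.nbx; ++bc)
      for (int br = 0; br < sim.nby; ++br)
        stat(br, bc) = sim.status[bc * sim.nby + br];
    snapshots.push_back(
        List::create(_["step"] = s, _["myelin_state"] = state,
                     _["oligo_status"] = stat));
  };

  sim.led_spawned = sim.led_converted = sim.led_pdeath = sim.led_rdeath =
      sim.led_premoved = sim.led_rremoved = 0;
  if (plan_step == 0) sim.apply_plan(plan);
  {
    double *row0 = new double[ncol_metrics];
    sim.record(0, sim.n_steps > 0 ? sim.relapse_active(0) : false, row0);
    for (int j = 0; j < ncol_metrics; ++j) metrics(0, j) = row0[j];
    delete[] row0;
  }
  if (want_snap[0]) take_snapshot(0);

  double row[ncol_metrics];
  for (int s = 1; s <= n; ++s) {
    sim.led_spawned = sim.led_converted = sim.led_pdeath = sim.led_rdeath =
        sim.led_premoved = sim.led_rremoved = 0;
    bool relapse = sim.relapse_active(s - 1);
    sim.spawn(relapse);
    sim.move_all();
    sim.present_antigen(s);
    sim.engage_and_degrade(s);
    sim.repair_step(s);
    sim.update_status();
    sim.disengage_on_floor();
    sim.deaths();
    if (s == plan_step) sim.apply_plan(plan);
    sim.accumulate_behaviour();
    sim.record(s, relapse, row);
    for (int j = 0; j < ncol_metrics; ++j) metrics(s, j) = row[j];
    if (want_snap[s]) take_snapshot(s);
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix beh(sim.NB, 3);
  for (int b = 0; b < sim.NB; ++b) {
    beh(b, 0) = sim.beh_myel[b];
    beh(b, 1) = sim.beh_nonmyel[b];
    beh(b, 2) = sim.beh_apop[b];
  }

  CharacterVector cn = CharacterVector::create(
      "step", "relapse", "primed", "pvm", "reactivated",
      "reactivated_parenchyma", "intact_frac", "partial_frac", "damaged_frac",
      "myelinating_frac", "nonmyelinating_frac", "apoptotic_frac", "spawned",
      "converted", "primed_deaths", "reactivated_deaths", "primed_removed",
      "reactivated_removed");
  colnames(metrics) = cn;

  return List::create(_["metrics"] = metrics, _["behaviour_steps"] = beh,
                      _["snapshots"] = snapshots);
}

//' @name bias_probs_cpp
//' @keywords internal
// [[Rcpp::export]]
NumericVector bias_probs_cpp(int dx, int dy, double beta, double k) {
  if (dx == 0 && dy == 0) stop("zero displacement");
  double d = std::sqrt((double)dx * dx + (double)dy * dy);
  double p[4];
  bias_probs(dx, dy, beta * std::exp(-k * d), p);
  NumericVector out = NumericVector::create(
      _["E"] = p[0], _["W"] = p[1], _["N"] = p[2], _["S"] = p[3]);
  return out;
}

//' @name nearest_eligible_cpp
//' @keywords internal
// [[Rcpp::export]]
SEXP nearest_eligible_cpp(IntegerMatrix state, int px, int row) {
  // state: lattice_height rows x parenchyma_width columns (1-based caller
  // coordinates; px may be <= 0 for cells left of the parenchyma)
  int H = state.nrow(), Wq = state.ncol();
  std::vector<int> st((size_t)Wq * H);
  std::vector<int> elig(Wq, 0);
  long total = 0;
  for (int pc = 0; pc < Wq; ++pc) {
    for (int r = 0; r < H; ++r) {
      st[(size_t)pc * H + r] = state(r, pc);
      if (state(r, pc) >= 2) {
        ++elig[pc];
        ++total;
      }
    }
  }
  int pc, r;
  double d;
  if (!nearest_eligible(st, elig, total, Wq, H, px - 1, row - 1, pc, r, d))
    return R_NilValue;
  return List::create(_["col"] = pc + 1, _["row"] = r + 1, _["distance"] = d);
}
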