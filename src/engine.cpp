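#include <Rcpp.h>
using namespace Rcpp;

// Movement engine shared by the cellular-automata (CA) and individual-based
// (IBM) passage models. Grids are n_i x n_j matrices with row 1 the
// upstream-most edge (success line) and row n_i the downstream-most edge
// (spawn line). All randomness comes from R's RNG (unif_rand / R::rlnorm),
// so set.seed() in R governs determinism, and the draw order (agent-major:
// spawn, [burst speed,] then one draw per move with a non-empty candidate
// group) matches the pure-R reference engine draw for draw.

struct StuckState {
  std::vector<int> buf;  // ring buffer of streamwise positions since reset
  int count;             // moves since reset
  int window, threshold, fallback_moves;
  bool block_mode;
  int mode;              // 0 normal, 1 fallback
  int fallback_left;

  StuckState(int w, int t, int f, bool block)
      : buf(w + 1), count(0), window(w), threshold(t), fallback_moves(f),
        block_mode(block), mode(0), fallback_left(0) {}

  void reset(int i) {
    count = 0;
    buf[0] = i;
  }

  // called after every move (including a forced stay); i = current row
  void update(int i) {
    if (mode == 1) {
      if (--fallback_left == 0) {
        mode = 0;
        reset(i);
      }
      return;
    }
    ++count;
    buf[count % (window + 1)] = i;
    if (count >= window) {
      bool assess = block_mode ? (count == window) : true;
      if (assess) {
        int i_old = buf[(count - window) % (window + 1)];
        if (i_old - i <= threshold) {
          mode = 1;
          fallback_left = fallback_moves;
        } else if (block_mode) {
          reset(i);
        }
      }
    }
  }
};

// pick uniformly among k candidates with a single unif_rand() draw
static inline int pick(int k) {
  int idx = (int)(unif_rand() * k);
  return idx >= k ? k - 1 : idx;
}

// Fill cand_i/cand_j with the viable cells of the highest-priority
// non-empty group and return its size (0 if no move is possible).
// viable(ii, jj, upstream_or_cross) decides admissibility per model.
template <typename Viable>
static int choose_group(int i, int j, int n_i, int n_j, int mode,
                        Viable viable, int *cand_i, int *cand_j,
                        bool *chose_downstream) {
  const int order_n[3] = {-1, 0, +1};  // normal: up, cross, down
  const int order_f[3] = {+1, 0, -1};  // fallback: down, cross, up
  const int *order = (mode == 0) ? order_n : order_f;
  for (int g = 0; g < 3; ++g) {
    int di = order[g];
    int ii = i + di;
    if (ii < 1 || ii > n_i) continue;
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      if (di == 0 && dj == 0) continue;
      int jj = j + dj;
      if (jj < 1 || jj > n_j) continue;
      if (!viable(ii, jj, di <= 0)) continue;
      cand_i[k] = ii;
      cand_j[k] = jj;
      ++k;
    }
    if (k > 0) {
      *chose_downstream = (di == 1);
      return k;
    }
  }
  return 0;
}

// [[Rcpp::export]]
List ca_engine_cpp(IntegerMatrix cls, int n_agents, int max_timesteps,
                   int stuck_window, int stuck_threshold, int fallback_moves,
                   bool block_mode) {
  const int n_i = cls.nrow(), n_j = cls.ncol();
  std::vector<int> spawnable;
  for (int j = 0; j < n_j; ++j)
    if (cls(n_i - 1, j) != 2) spawnable.push_back(j + 1);
  if (spawnable.empty())
    stop("Downstream edge is entirely boundary; nowhere to spawn.");

  IntegerVector outcome(n_agents), moves(n_agents), spawn_j(n_agents);
  IntegerVector final_i(n_agents), final_j(n_agents);
  RNGScope rng;
  int cand_i[3], cand_j[3];

  for (int a = 0; a < n_agents; ++a) {
    int j = spawnable[pick((int)spawnable.size())];
    int i = n_i;
    spawn_j[a] = j;
    StuckState st(stuck_window, stuck_threshold, fallback_moves, block_mode);
    st.reset(i);
    int out = 2;  // timed_out unless it passes
    int m = 0;
    if (i == 1) out = 1;  // degenerate single-row grid
    for (int t = 0; t < max_timesteps && out == 2; ++t) {
      bool down;
      auto viable = [&](int ii, int jj, bool) {
        return cls(ii - 1, jj - 1) == 0;
      };
      int k = choose_group(i, j, n_i, n_j, st.mode, viable, cand_i, cand_j, &down);
      if (k > 0) {
        int c = pick(k);
        i = cand_i[c];
        j = cand_j[c];
      }
      ++m;
      if (i == 1) {
        out = 1;
        break;
      }
      st.update(i);
    }
    outcome[a] = out;
    moves[a] = m;
    final_i[a] = i;
    final_j[a] = j;
  }
  return List::create(_["outcome"] = outcome, _["moves"] = moves,
                      _["spawn_j"] = spawn_j, _["final_i"] = final_i,
                      _["final_j"] = final_j);
}

// [[Rcpp::export]]
List ibm_engine_cpp(NumericMatrix speed, int n_agents, int max_timesteps,
                    int stuck_window, int stuck_threshold, int fallback_moves,
                    bool block_mode, double meanlog, double sdlog,
                    double burst_duration, double cell_size,
                    double diagonal_factor, bool assisted_fallback) {
  const int n_i = speed.nrow(), n_j = speed.ncol();
  std::vector<int> spawnable;
  for (int j = 0; j < n_j; ++j)
    if (!NumericMatrix::is_na(speed(n_i - 1, j))) spawnable.push_back(j + 1);
  if (spawnable.empty())
    stop("Downstream edge is entirely boundary; nowhere to spawn.");

  IntegerVector outcome(n_agents), moves(n_agents), spawn_j(n_agents);
  NumericVector elapsed(n_agents), burst(n_agents);
  IntegerVector final_i(n_agents), final_j(n_agents);
  RNGScope rng;
  int cand_i[3], cand_j[3];

  for (int a = 0; a < n_agents; ++a) {
    int j = spawnable[pick((int)spawnable.size())];
    int i = n_i;
    spawn_j[a] = j;
    double v = R::rlnorm(meanlog, sdlog);
    burst[a] = v;
    StuckState st(stuck_window, stuck_threshold, fallback_moves, block_mode);
    st.reset(i);
    int out = 2;
    int m = 0;
    double tsum = 0.0;
    if (i == 1) out = 1;
    for (int t = 0; t < max_timesteps && out == 2; ++t) {
      bool down = false;
      auto viable = [&](int ii, int jj, bool up_or_cross) {
        double u = speed(ii - 1, jj - 1);
        if (NumericMatrix::is_na(u)) return false;
        if (up_or_cross) return v - u > 0.0;
        return true;  // downstream moves are always viable in wet cells
      };
      int k = choose_group(i, j, n_i, n_j, st.mode, viable, cand_i, cand_j, &down);
      if (k > 0) {
        int c = pick(k);
        int ni = cand_i[c], nj = cand_j[c];
        bool diag = (ni != i) && (nj != j);
        double dist = cell_size * (diag ? diagonal_factor : 1.0);
        double u = speed(ni - 1, nj - 1);
        double rel = down ? v + u : v - u;
        if (!down || assisted_fallback) tsum += dist / rel;
        i = ni;
        j = nj;
      }
      ++m;
      if (i == 1) {
        out = 1;
        break;
      }
      if (tsum > burst_duration) {
        out = 3;  // exhausted
        break;
      }
      st.update(i);
    }
    outcome[a] = out;
    moves[a] = m;
    elapsed[a] = tsum;
    final_i[a] = i;
    final_j[a] = j;
  }
  return List::create(_["outcome"] = outcome, _["moves"] = moves,
                      _["spawn_j"] = spawn_j, _["elapsed"] = elapsed,
                      _["burst"] = burst, _["final_i"] = final_i,
                      _["final_j"] = final_j);
}
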