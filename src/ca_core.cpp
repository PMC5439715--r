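#include <Rcpp.h>
using namespace Rcpp;

// Lattice codes: 0 = empty, 1 = viable (proliferative or quiescent),
// 2 = NPMA (stably arrested, metabolically active).
//
// One call = one day. Random sequential update: occupied sites are visited
// in a freshly shuffled order; cells created or moved during the sweep carry
// a stamp so they act at most once per day. All randomness comes from R's
// RNG (unif_rand), so set.seed() in R makes runs bit-identical.

static const int DX[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DY[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

static inline int ri(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
List ca_step_cpp(IntegerMatrix state, IntegerMatrix maturity,
                 IntegerMatrix dormancy, double p_a, double p_d, double mu,
                 int m, int R, double npma_clearance, int capacity) {
  int L = state.nrow();
  if (state.ncol() != L) stop("lattice must be square");
  if (p_a < 0 || p_a > 1 || p_d < 0 || p_d > 1 || p_a + p_d > 1.0 + 1e-12)
    stop("need 0 <= p_a, p_d and p_a + p_d <= 1");

  // gather occupied sites
  std::vector<int> occ;
  occ.reserve(4096);
  int total = 0;
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i)
      if (state(i, j) != 0) { occ.push_back(i + j * L); ++total; }

  // local-inhibition mask: sites within Chebyshev distance R of any NPMA cell
  LogicalMatrix suppressed(0, 0);
  bool use_mask = R > 0;
  if (use_mask) {
    suppressed = LogicalMatrix(L, L);
    for (size_t s = 0; s < occ.size(); ++s) {
      int i = occ[s] % L, j = occ[s] / L;
      if (state(i, j) != 2) continue;
      for (int di = -R; di <= R; ++di) {
        for (int dj = -R; dj <= R; ++dj) {
          int ni = i + di, nj = j + dj;
          if (ni >= 0 && ni < L && nj >= 0 && nj < L)
            suppressed(ni, nj) = true;
        }
      }
    }
  }

  // Fisher-Yates shuffle of the visit order
  for (int s = (int)occ.size() - 1; s > 0; --s) {
    int t = ri(s + 1);
    std::swap(occ[s], occ[t]);
  }

  IntegerMatrix acted(L, L); // 1 = this site's occupant already acted today

  int births = 0, deaths = 0, cleared = 0;
  for (size_t s = 0; s < occ.size(); ++s) {
    int i = occ[s] % L, j = occ[s] / L;
    if (state(i, j) == 0 || acted(i, j)) continue;
    acted(i, j) = 1;

    if (state(i, j) == 2) { // NPMA: cleared or persists; never divides
      if (npma_clearance > 0 && unif_rand() < npma_clearance) {
        state(i, j) = 0; maturity(i, j) = 0; dormancy(i, j) = 0;
        --total; ++cleared;
      } else {
        if (dormancy(i, j) < INT_MAX - 1) dormancy(i, j) += 1;
      }
      continue;
    }

    // viable cell: one draw decides death vs division-attempt vs persist,
    // so the low-density per-step growth factor is exactly 1 + p_d - p_a
    double u = unif_rand();
    if (u < p_a) {
      state(i, j) = 0; maturity(i, j) = 0; dormancy(i, j) = 0;
      --total; ++deaths;
      continue;
    }

    // free Moore neighbours
    int freeN[8], nfree = 0;
    for (int d = 0; d < 8; ++d) {
      int ni = i + DX[d], nj = j + DY[d];
      if (ni >= 0 && ni < L && nj >= 0 && nj < L && state(ni, nj) == 0)
        freeN[nfree++] = d;
    }

    bool divided = false;
    if (u < p_a + p_d && nfree > 0 && maturity(i, j) >= m &&
        total < capacity && !(use_mask && suppressed(i, j))) {
      int d = freeN[ri(nfree)];
      int ni = i + DX[d], nj = j + DY[d];
      state(ni, nj) = 1;
      maturity(ni, nj) = 0;
      dormancy(ni, nj) = 0;
      acted(ni, nj) = 1; // daughter acts tomorrow
      dormancy(i, j) = 0;
      ++total; ++births;
      divided = true;
    }

    if (!divided) {
      if (nfree > 0 && mu > 0) {
        // migration: expected `mu` attempts/day at a random Moore direction,
        // each succeeding only when the chosen site is free
        int natt = (int)mu + (unif_rand() < (mu - (int)mu) ? 1 : 0);
        int ci = i, cj = j;
        for (int a = 0; a < natt; ++a) {
          int d = ri(8);
          int ni = ci + DX[d], nj = cj + DY[d];
          if (ni >= 0 && ni < L && nj >= 0 && nj < L && state(ni, nj) == 0) {
            state(ni, nj) = 1;
            maturity(ni, nj) = maturity(ci, cj);
            dormancy(ni, nj) = dormancy(ci, cj);
            acted(ni, nj) = 1;
            state(ci, cj) = 0; maturity(ci, cj) = 0; dormancy(ci, cj) = 0;
            acted(ci, cj) = 1;
            ci = ni; cj = nj;
          }
        }
        i = ci; j = cj;
      }
      dormancy(i, j) += 1;
    }
    if (maturity(i, j) < m) maturity(i, j) += 1;
  }

  return List::create(_["births"] = births, _["deaths"] = deaths,
                      _["npma_cleared"] = cleared, _["total"] = total);
}

// Counts of proliferative (viable with a free Moore neighbour), quiescent
// (viable, fully enclosed) and NPMA cells.
// [[Rcpp::export]]
IntegerVector ca_counts_cpp(IntegerMatrix state) {
  int L = state.nrow();
  int np = 0, nq = 0, nn = 0;
  for (int j = 0; j < L; ++j) {
    for (int i = 0; i < L; ++i) {
      int st = state(i, j);
      if (st == 0) continue;
      if (st == 2) { ++nn; continue; }
      bool freeN = false;
      for (int d = 0; d < 8 && !freeN; ++d) {
        int ni = i + DX[d], nj = j + DY[d];
        if (ni >= 0 && ni < L && nj >= 0 && nj < L && state(ni, nj) == 0)
          freeN = true;
      }
      if (freeN) ++np; else ++nq;
    }
  }
  return IntegerVector::create(_["proliferative"] = np, _["quiescent"] = nq,
                               _["npma"] = nn);
}

// [[Rcpp::export]]
LogicalMatrix ca_mask_cpp(IntegerMatrix state, int R) {
  int L = state.nrow();
  LogicalMatrix out(L, L);
  if (R < 0) stop("R must be >= 0");
  for (int j = 0; j < L; ++j) {
    for (int i = 0; i < L; ++i) {
      if (state(i, j) != 2) continue;
      for (int di = -R; di <= R; ++di) {
        for (int dj = -R; dj <= R; ++dj) {
          int ni = i + di, nj = j + dj;
          if (ni >= 0 && ni < L && nj >= 0 && nj < L) out(ni, nj) = true;
        }
      }
    }
  }
  return out;
}
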