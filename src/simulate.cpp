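#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// State codes follow the canonical order AU=1, UR=2, AR=3, UU=4.
//
// This engine mirrors the reference R implementation bit-for-bit: per step
// it draws one uniform per site in site order (inverse-CDF over the fixed
// state order), and at replication steps one uniform per site.  All
// floating-point expressions are written in the same operation order as the
// R code so both engines produce identical trajectories under the same seed.

// [[Rcpp::export]]
IntegerMatrix run_sim_cpp(IntegerVector init, int nSteps, int stepsPerCycle,
                          bool replication,
                          double kMeA, double kMeR, double kDmA, double kDmR,
                          NumericVector kexpA, NumericVector kexpR,
                          double kExMinusA, double kExMinusR,
                          int r, bool includeSelf,
                          double multUU, bool exchangeMult) {
  const int N = init.size();
  IntegerMatrix out(nSteps + 1, N);
  std::vector<int> cur(init.begin(), init.end());
  std::vector<int> nxt(N);
  std::vector<int> csA(N + 1), csR(N + 1);
  for (int j = 0; j < N; ++j) out(0, j) = cur[j];

  const double denomFull = 2.0 * r + 1.0;
  const double denomSelf = 2.0 * r;

  for (int t = 1; t <= nSteps; ++t) {
    // prefix sums of mark carriers (AR carries both marks)
    csA[0] = 0; csR[0] = 0;
    for (int j = 0; j < N; ++j) {
      int s = cur[j];
      csA[j + 1] = csA[j] + ((s == 1 || s == 3) ? 1 : 0);
      csR[j + 1] = csR[j] + ((s == 2 || s == 3) ? 1 : 0);
    }
    for (int j = 0; j < N; ++j) {
      int lo = j - r; if (lo < 0) lo = 0;
      int hi = j + r; if (hi > N - 1) hi = N - 1;
      int cntA = csA[hi + 1] - csA[lo];
      int cntR = csR[hi + 1] - csR[lo];
      double thetaA, thetaR;
      int s = cur[j];
      if (includeSelf) {
        thetaA = cntA / denomFull;
        thetaR = cntR / denomFull;
      } else {
        cntA -= (s == 1 || s == 3) ? 1 : 0;
        cntR -= (s == 2 || s == 3) ? 1 : 0;
        if (r == 0) { thetaA = 0.0; thetaR = 0.0; }
        else { thetaA = cntA / denomSelf; thetaR = cntR / denomSelf; }
      }

      double addA = kMeA * thetaA + kexpA[j];
      double addR = kMeR * thetaR + kexpR[j];
      double remA = kDmA * thetaR + kExMinusA;
      double remR = kDmR * thetaA + kExMinusR;
      double uuToAU, uuToUR;
      if (exchangeMult) {
        uuToAU = multUU * addA;
        uuToUR = multUU * addR;
      } else {
        uuToAU = multUU * (kMeA * thetaA) + kexpA[j];
        uuToUR = multUU * (kMeR * thetaR) + kexpR[j];
      }

      double pAU, pUR, pAR, exitSum;
      switch (s) {
      case 4:  // UU
        exitSum = uuToAU + uuToUR;
        pAU = uuToAU; pUR = uuToUR; pAR = 0.0;
        break;
      case 1:  // AU
        exitSum = addR + remA;
        pAU = 1.0 - exitSum; pUR = 0.0; pAR = addR;
        break;
      case 2:  // UR
        exitSum = addA + remR;
        pAU = 0.0; pUR = 1.0 - exitSum; pAR = addA;
        break;
      default: // AR
        exitSum = remA + remR;
        pAU = remR; pUR = remA; pAR = 1.0 - exitSum;
        break;
      }
      if (exitSum > 1.0 + 1e-12)
        stop("one-step exit probability %.4f > 1 at site %d: parameters "
             "violate the small-time-step assumption", exitSum, j + 1);
      double cum1 = pAU;
      double cum2 = cum1 + pUR;
      double cum3 = cum2 + pAR;
      double u = unif_rand();
      int ns = 1 + (u >= cum1 ? 1 : 0) + (u >= cum2 ? 1 : 0) +
               (u >= cum3 ? 1 : 0);
      nxt[j] = ns;
    }
    if (replication && (t % stepsPerCycle == 0)) {
      for (int j = 0; j < N; ++j)
        if (unif_rand() < 0.5) nxt[j] = 4;
    }
    for (int j = 0; j < N; ++j) {
      cur[j] = nxt[j];
      out(t, j) = cur[j];
    }
  }
  return out;
}
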