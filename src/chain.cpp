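// Metropolis-Hastings kernel over states m(Phi, X).
//
// The proposal mixes uniform single-link toggles (probability rho) with a
// uniform draw over all (parameter, alternative grid value) neighbors.
// Neighbor counts are constant across states, so the Hastings correction is
// exactly 1 and acceptance reduces to min(1, exp(delta log-likelihood)).
//
// The state log-likelihood is always recomputed from the sufficient counts
// (|X|, |I11|, |I10|, |I01|, |I00|) in O(1); deltas are never accumulated,
// so there is no numerical drift over long chains. A link toggle updates
// the counts in time proportional to its cross set via the 0<->1
// transitions of the per-interaction explanation counter.
//
// Visit counters are maintained by run-length bookkeeping: each recorded
// step counts the state *after* that step's proposal is resolved, and a
// counter is flushed only when its entity changes, so recording is O(1)
// per step regardless of the number of links.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List chain_kernel(List crossSets, LogicalVector perturbed,
                  double nPossibleLinks,
                  NumericVector lambdaGrid, NumericVector alphaGrid,
                  NumericVector betaGrid,
                  int startLambda, int startAlpha, int startBeta,
                  double rho, bool paramMoves,
                  double burnInSteps, double sampleSteps,
                  bool recordStates, int traceThin) {
  const int nL = crossSets.size();
  const int nC = perturbed.size();
  std::vector<std::vector<int> > cross(nL);
  for (int l = 0; l < nL; ++l) {
    IntegerVector cs = crossSets[l];
    cross[l].reserve(cs.size());
    for (int k = 0; k < cs.size(); ++k) cross[l].push_back(cs[k] - 1);
  }
  long long nD = 0;
  for (int e = 0; e < nC; ++e) if (perturbed[e]) ++nD;

  const int nLam = lambdaGrid.size(), nAl = alphaGrid.size(),
            nBe = betaGrid.size();
  std::vector<double> logLam(nLam), log1mLam(nLam), logA(nAl), log1mA(nAl),
                      logB(nBe), log1mB(nBe);
  for (int i = 0; i < nLam; ++i) {
    logLam[i] = std::log(lambdaGrid[i]);
    log1mLam[i] = std::log1p(-lambdaGrid[i]);
  }
  for (int i = 0; i < nAl; ++i) {
    logA[i] = std::log(alphaGrid[i]);
    log1mA[i] = std::log1p(-alphaGrid[i]);
  }
  for (int i = 0; i < nBe; ++i) {
    logB[i] = std::log(betaGrid[i]);
    log1mB[i] = std::log1p(-betaGrid[i]);
  }
  const int nParamNb = (nLam - 1) + (nAl - 1) + (nBe - 1);

  // state
  std::vector<char> inX(nL, 0);
  std::vector<int> expl(nC, 0);
  int nX = 0, iL = startLambda, iA = startAlpha, iB = startBeta;
  long long n11 = 0, n01 = 0;
  const double Lp = nPossibleLinks;

  // log-likelihood from sufficient counts, O(1)
  #define LOGL(NX, N11, N01, IL, IA, IB)                                  \
    ((NX) * logLam[IL] + (Lp - (NX)) * log1mLam[IL] +                     \
     (double)(nD - (N11)) * logA[IA] +                                    \
     (double)((nC - nD) - (N01)) * log1mA[IA] +                           \
     (double)(N01) * logB[IB] + (double)(N11) * log1mB[IB])

  double curLL = LOGL(nX, n11, n01, iL, iA, iB);

  // recording state
  const double S = sampleSteps;
  NumericVector linkVisits(nL, 0.0);
  NumericVector lamVisits(nLam, 0.0), alVisits(nAl, 0.0), beVisits(nBe, 0.0);
  std::vector<double> sinceLink(nL, 0.0);
  double sinceLam = 0, sinceAl = 0, sinceBe = 0, sinceState = 0;
  unsigned int curMask = 0;
  NumericVector stateVisits(recordStates ? (1u << nL) : 0, 0.0);
  std::vector<double> trace;
  if (traceThin > 0 && S > 0) trace.reserve((size_t)(S / traceThin) + 1);

  long long accepted = 0;
  const long long total = (long long)(burnInSteps + sampleSteps);
  const long long burn = (long long)burnInSteps;

  GetRNGstate();
  for (long long step = 1; step <= total; ++step) {
    const bool rec = step > burn;
    const double r = (double)(step - burn);  // recorded-step index when rec
    if (rec && step == burn + 1) {
      for (int l = 0; l < nL; ++l) if (inX[l]) sinceLink[l] = 1.0;
      sinceLam = sinceAl = sinceBe = sinceState = 1.0;
    }

    bool isLink = !paramMoves || unif_rand() < rho;
    if (isLink && nL > 0) {
      int l = (int)(unif_rand() * nL);
      if (l >= nL) l = nL - 1;
      const std::vector<int>& cs = cross[l];
      long long d11 = 0, d01 = 0;
      if (!inX[l]) {
        for (size_t k = 0; k < cs.size(); ++k)
          if (expl[cs[k]] == 0) { if (perturbed[cs[k]]) ++d11; else ++d01; }
      } else {
        for (size_t k = 0; k < cs.size(); ++k)
          if (expl[cs[k]] == 1) { if (perturbed[cs[k]]) --d11; else --d01; }
      }
      const int dX = inX[l] ? -1 : 1;
      const double newLL = LOGL(nX + dX, n11 + d11, n01 + d01, iL, iA, iB);
      const double delta = newLL - curLL;
      if (delta >= 0.0 || unif_rand() < std::exp(delta)) {
        ++accepted;
        const int d = dX;
        for (size_t k = 0; k < cs.size(); ++k) expl[cs[k]] += d;
        if (rec) {
          if (inX[l]) linkVisits[l] += r - sinceLink[l];  // turning off
          else sinceLink[l] = r;                           // turning on
          if (recordStates) {
            stateVisits[curMask] += r - sinceState;
            sinceState = r;
          }
        }
        inX[l] = !inX[l];
        nX += dX; n11 += d11; n01 += d01;
        if (recordStates) curMask ^= (1u << l);
        curLL = newLL;
      }
    } else if (!isLink) {
      int rr = (int)(unif_rand() * nParamNb);
      if (rr >= nParamNb) rr = nParamNb - 1;
      int which, newIdx;
      if (rr < nLam - 1) {
        which = 0; newIdx = (rr >= iL) ? rr + 1 : rr;
      } else if (rr < (nLam - 1) + (nAl - 1)) {
        rr -= nLam - 1;
        which = 1; newIdx = (rr >= iA) ? rr + 1 : rr;
      } else {
        rr -= (nLam - 1) + (nAl - 1);
        which = 2; newIdx = (rr >= iB) ? rr + 1 : rr;
      }
      const double newLL = LOGL(nX, n11, n01,
                                which == 0 ? newIdx : iL,
                                which == 1 ? newIdx : iA,
                                which == 2 ? newIdx : iB);
      const double delta = newLL - curLL;
      if (delta >= 0.0 || unif_rand() < std::exp(delta)) {
        ++accepted;
        if (rec) {
          if (which == 0) { lamVisits[iL] += r - sinceLam; sinceLam = r; }
          else if (which == 1) { alVisits[iA] += r - sinceAl; sinceAl = r; }
          else { beVisits[iB] += r - sinceBe; sinceBe = r; }
        }
        if (which == 0) iL = newIdx;
        else if (which == 1) iA = newIdx;
        else iB = newIdx;
        curLL = newLL;
      }
    }

    if (rec && traceThin > 0 && ((long long)r % traceThin == 0))
      trace.push_back(curLL);
  }
  PutRNGstate();

  // final flush at virtual recorded step S + 1
  if (S > 0) {
    const double rEnd = S + 1.0;
    for (int l = 0; l < nL; ++l)
      if (inX[l]) linkVisits[l] += rEnd - sinceLink[l];
    lamVisits[iL] += rEnd - sinceLam;
    alVisits[iA] += rEnd - sinceAl;
    beVisits[iB] += rEnd - sinceBe;
    if (recordStates) stateVisits[curMask] += rEnd - sinceState;
  }

  IntegerVector finalLinks;
  {
    std::vector<int> fl;
    for (int l = 0; l < nL; ++l) if (inX[l]) fl.push_back(l + 1);
    finalLinks = wrap(fl);
  }
  return List::create(
    _["linkVisits"] = linkVisits,
    _["lambdaVisits"] = lamVisits,
    _["alphaVisits"] = alVisits,
    _["betaVisits"] = beVisits,
    _["totalRecorded"] = S,
    _["accepted"] = (double)accepted,
    _["totalProposals"] = (double)total,
    _["stateVisits"] = stateVisits,
    _["likelihoodTrace"] = wrap(trace),
    _["finalLinks"] = finalLinks,
    _["finalParameters"] = IntegerVector::create(iL + 1, iA + 1, iB + 1),
    _["finalLogLikelihood"] = curLL);
}
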