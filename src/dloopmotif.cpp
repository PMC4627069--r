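#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sequences are integer-encoded: A,C,G,T = 0..3; 4 = N or an erased
// (masked) position. N contributes odds ratio 1 to site likelihoods and
// probability 1 to the background term.

// One ZOOPS E-step plus sufficient statistics for the M-step.
// log_ppm: width x 4 natural-log motif column probabilities.
// log_bg / bg: natural-log and plain background probabilities.
// gamma: prior probability that a sequence carries a site.
// both: also scan the reverse strand.
// Returns expected base counts per motif column (site posteriors folded
// onto the motif orientation), the mean per-sequence site posterior, the
// full data log-likelihood, and each sequence's best slot.
// [[Rcpp::export]]
List zoops_estep_cpp(List seqs, NumericMatrix log_ppm, NumericVector log_bg,
                     NumericVector bg, double gamma, bool both) {
  const int w = log_ppm.nrow();
  const int n = seqs.size();
  NumericMatrix counts(w, 4);
  double loglik = 0.0, gamma_sum = 0.0;
  IntegerVector best_off(n), best_strand(n);
  NumericVector best_post(n), site_post(n);

  // log-odds per column/base (row-major, 5 slots per column so that the
  // N/masked code 4 scores 0), forward and reverse-complement orientation
  std::vector<double> lo(5 * w, 0.0), lorc(5 * w, 0.0);
  for (int k = 0; k < w; ++k)
    for (int b = 0; b < 4; ++b)
      lo[5 * k + b] = log_ppm(k, b) - log_bg[b];
  for (int k = 0; k < w; ++k)
    for (int b = 0; b < 4; ++b)
      lorc[5 * k + b] = lo[5 * (w - 1 - k) + (3 - b)];

  const double log1mg = (gamma >= 1.0) ? R_NegInf : std::log1p(-gamma);
  const double loggamma = (gamma <= 0.0) ? R_NegInf : std::log(gamma);

  for (int i = 0; i < n; ++i) {
    IntegerVector xi = seqs[i];
    const int L = xi.size();
    const int m1 = L - w + 1;
    if (m1 <= 0) stop("sequence %d shorter than motif width", i + 1);
    const int m = both ? 2 * m1 : m1;
    const int *x = INTEGER(xi);

    std::vector<double> slot(m);
    double maxl = R_NegInf;
    for (int j = 0; j < m1; ++j) {
      double s = 0.0;
      const int *xj = x + j;
      for (int k = 0; k < w; ++k) s += lo[5 * k + xj[k]];
      slot[j] = s;
      if (s > maxl) maxl = s;
    }
    if (both) {
      for (int j = 0; j < m1; ++j) {
        double s = 0.0;
        const int *xj = x + j;
        for (int k = 0; k < w; ++k) s += lorc[5 * k + xj[k]];
        slot[m1 + j] = s;
        if (s > maxl) maxl = s;
      }
    }

    // log-sum-exp over {no site} u {site at each slot}
    const double lg_site = loggamma - std::log((double)m);
    double hi = std::max(log1mg, lg_site + maxl);
    double z = std::exp(log1mg - hi);
    for (int j = 0; j < m; ++j) z += std::exp(lg_site + slot[j] - hi);
    const double lse = hi + std::log(z);
    if (!R_FINITE(lse)) stop("non-finite likelihood in E-step");

    // background term over non-N positions
    double lbg = 0.0;
    for (int p = 0; p < L; ++p)
      if (x[p] < 4) lbg += log_bg[x[p]];
    loglik += lse + lbg;

    const double p_nosite = std::exp(log1mg - lse);
    site_post[i] = 1.0 - p_nosite;
    gamma_sum += site_post[i];

    double bmax = -1.0; int boff = -1, bstr = 0;
    const double log_zmin = std::log(1e-12);  // slots below this add nothing
    for (int j = 0; j < m; ++j) {
      const double lz = lg_site + slot[j] - lse;
      const bool rev = j >= m1;
      const int off = rev ? j - m1 : j;
      const double zj = (lz > -700.0) ? std::exp(lz) : 0.0;
      if (zj > bmax) { bmax = zj; boff = off; bstr = rev ? 1 : 0; }
      if (lz < log_zmin) continue;
      // N/masked positions contribute no observed counts: their
      // complete-data likelihood term is constant in the PPM, so the
      // exact M-step maximizer uses residue counts only.
      if (!rev) {
        for (int k = 0; k < w; ++k) {
          int b = x[off + k];
          if (b < 4) counts(k, b) += zj;
        }
      } else {
        for (int k = 0; k < w; ++k) {
          int b = x[off + w - 1 - k];
          if (b < 4) counts(k, 3 - b) += zj;
        }
      }
    }
    best_off[i] = boff;
    best_strand[i] = bstr;
    best_post[i] = bmax;
  }

  return List::create(_["counts"] = counts,
                      _["gamma_mean"] = gamma_sum / n,
                      _["loglik"] = loglik,
                      _["best_off"] = best_off,
                      _["best_strand"] = best_strand,
                      _["best_post"] = best_post,
                      _["site_post"] = site_post);
}

// Global (Needleman-Wunsch) alignment with affine gaps; a gap run of
// length L costs gap_open + L * gap_ext. Codes 0..3 = A,C,G,T; 4 = N,
// which matches nothing (mismatch even against N). Returns the optimal
// score, and matches / alignment length from one optimal traceback.
// [[Rcpp::export]]
List nw_identity_cpp(IntegerVector xi, IntegerVector yi, double match,
                     double mismatch, double gap_open, double gap_ext) {
  const int n = xi.size(), m = yi.size();
  const int *x = INTEGER(xi), *y = INTEGER(yi);
  const double NEG = -1e30;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * W] = -(gap_open + i * gap_ext);
  for (int j = 1; j <= m; ++j) Y[j] = -(gap_open + j * gap_ext);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s =
          (x[i - 1] == y[j - 1] && x[i - 1] < 4) ? match : mismatch;
      const int d = (i - 1) * W + (j - 1);
      double best = M[d];
      if (X[d] > best) best = X[d];
      if (Y[d] > best) best = Y[d];
      M[i * W + j] = best + s;
      const int u = (i - 1) * W + j;
      double xb = M[u] - gap_open - gap_ext;
      if (X[u] - gap_ext > xb) xb = X[u] - gap_ext;
      if (Y[u] - gap_open - gap_ext > xb) xb = Y[u] - gap_open - gap_ext;
      X[i * W + j] = xb;
      const int l = i * W + (j - 1);
      double yb = M[l] - gap_open - gap_ext;
      if (Y[l] - gap_ext > yb) yb = Y[l] - gap_ext;
      if (X[l] - gap_open - gap_ext > yb) yb = X[l] - gap_open - gap_ext;
      Y[i * W + j] = yb;
    }
  }
  // traceback (layer 0 = M, 1 = X, 2 = Y), preferring M on ties
  int i = n, j = m, layer = 0;
  double fin = M[n * W + m];
  if (X[n * W + m] > fin) { fin = X[n * W + m]; layer = 1; }
  if (Y[n * W + m] > fin) { fin = Y[n * W + m]; layer = 2; }
  long matches = 0, alen = 0;
  const double tol = 1e-9;
  while (i > 0 || j > 0) {
    ++alen;
    if (layer == 0) {
      if (i == 0 || j == 0) stop("traceback error");
      if (x[i - 1] == y[j - 1] && x[i - 1] < 4) ++matches;
      const double s =
          (x[i - 1] == y[j - 1] && x[i - 1] < 4) ? match : mismatch;
      const double prev = M[i * W + j] - s;
      const int d = (i - 1) * W + (j - 1);
      if (std::fabs(M[d] - prev) < tol) layer = 0;
      else if (std::fabs(X[d] - prev) < tol) layer = 1;
      else layer = 2;
      --i; --j;
    } else if (layer == 1) {
      if (i == 0) stop("traceback error");
      const double v = X[i * W + j];
      const int u = (i - 1) * W + j;
      if (std::fabs(M[u] - gap_open - gap_ext - v) < tol) layer = 0;
      else if (std::fabs(X[u] - gap_ext - v) < tol) layer = 1;
      else layer = 2;
      --i;
    } else {
      if (j == 0) stop("traceback error");
      const double v = Y[i * W + j];
      const int l = i * W + (j - 1);
      if (std::fabs(M[l] - gap_open - gap_ext - v) < tol) layer = 0;
      else if (std::fabs(Y[l] - gap_ext - v) < tol) layer = 2;
      else layer = 1;
      --j;
    }
  }
  return List::create(_["score"] = fin, _["matches"] = (double)matches,
                      _["alen"] = (double)alen);
}

// Glocal (global-in-profile, local-in-sequence) Viterbi for a linear
// match/insert/delete profile, scored in log2-odds against the background.
// x: encoded sequence. l2m: Lp x 4 log2 match-emission odds. l2i: 4-vector
// log2 insert-emission odds. tb: log2 begin transitions c(->M1, ->D1).
// tm, ti, td: Lp x 3 log2 transitions from M_j / I_j / D_j to
// {M_{j+1}, I_j, D_{j+1}}; at j = Lp the first slot leads to End.
// Insert states exist for j = 1..Lp-1; flanking inserts are free flanks.
// [[Rcpp::export]]
List profile_viterbi_cpp(IntegerVector xi, NumericMatrix l2m,
                         NumericVector l2i, NumericVector tb,
                         NumericMatrix tm, NumericMatrix ti,
                         NumericMatrix td) {
  const int Lp = l2m.nrow();
  const int n = xi.size();
  const int *x = INTEGER(xi);
  const double NEG = -1e30;

  // V*(j, i): best log2-odds of a path ending in state * at profile
  // position j with i consumed residues. S*: 0-based start of the first
  // consumed residue (i when none consumed yet).
  NumericMatrix VM(Lp + 1, n + 1), VI(Lp + 1, n + 1), VD(Lp + 1, n + 1);
  IntegerMatrix SM(Lp + 1, n + 1), SI(Lp + 1, n + 1), SD(Lp + 1, n + 1);
  std::fill(VM.begin(), VM.end(), NEG);
  std::fill(VI.begin(), VI.end(), NEG);
  std::fill(VD.begin(), VD.end(), NEG);

  for (int i = 0; i <= n; ++i) { VD(1, i) = tb[1]; SD(1, i) = i; }
  for (int j = 1; j <= Lp; ++j) {
    for (int i = 0; i <= n; ++i) {
      if (i >= 1) {
        int b = x[i - 1];
        double em = (b < 4) ? l2m(j - 1, b) : 0.0;
        double best; int src;
        if (j == 1) { best = tb[0]; src = i - 1; }
        else {
          best = VM(j - 1, i - 1) + tm(j - 2, 0); src = SM(j - 1, i - 1);
          double v = VI(j - 1, i - 1) + ti(j - 2, 0);
          if (v > best) { best = v; src = SI(j - 1, i - 1); }
          v = VD(j - 1, i - 1) + td(j - 2, 0);
          if (v > best) { best = v; src = SD(j - 1, i - 1); }
        }
        VM(j, i) = best + em; SM(j, i) = src;
      }
      if (j >= 2) {  // delete (VD(1,.) initialized above)
        double best = VM(j - 1, i) + tm(j - 2, 2); int src = SM(j - 1, i);
        double v = VI(j - 1, i) + ti(j - 2, 2);
        if (v > best) { best = v; src = SI(j - 1, i); }
        v = VD(j - 1, i) + td(j - 2, 2);
        if (v > best) { best = v; src = SD(j - 1, i); }
        VD(j, i) = best; SD(j, i) = src;
      }
      if (j <= Lp - 1 && i >= 1) {  // insert after match j
        int b = x[i - 1];
        double em = (b < 4) ? l2i[b] : 0.0;
        double best = VM(j, i - 1) + tm(j - 1, 1); int src = SM(j, i - 1);
        double v = VI(j, i - 1) + ti(j - 1, 1);
        if (v > best) { best = v; src = SI(j, i - 1); }
        v = VD(j, i - 1) + td(j - 1, 1);
        if (v > best) { best = v; src = SD(j, i - 1); }
        VI(j, i) = best + em; SI(j, i) = src;
      }
    }
  }

  double score = NEG; int bstart = 0, bend = 0;
  for (int i = 0; i <= n; ++i) {
    double vm = VM(Lp, i) + tm(Lp - 1, 0);
    double vd = VD(Lp, i) + td(Lp - 1, 0);
    if (vm > score) { score = vm; bstart = SM(Lp, i); bend = i; }
    if (vd > score) { score = vd; bstart = SD(Lp, i); bend = i; }
  }
  return List::create(_["score"] = score, _["start"] = bstart,
                      _["end"] = bend);
}
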