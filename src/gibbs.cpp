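// Gibbs sampler for the joint model: truncated-normal augmentation of the
// probit hazard rows, conjugate updates for the Gaussian blocks, and
// Newton-proposal Metropolis-Hastings updates of the two hazard
// coefficient blocks with the latents collapsed (the augmentation random
// walk is far too slow for the weakly identified death-model
// associations). Mirrors the reference R implementation (gibbs_chain);
// the two are compared draw-distribution-wise in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// stable truncated normal: w ~ N(mu, 1) conditioned on w > 0 (pos = true)
// or w <= 0, via inverse-CDF sampling in the log domain
static double rtnorm01(double mu, bool pos) {
  if (!pos) mu = -mu;
  double lt = std::log(R::unif_rand()) + R::pnorm(-mu, 0.0, 1.0, 0, 1);
  double z = R::qnorm(lt, 0.0, 1.0, 0, 1);
  double w = mu + z;
  return pos ? w : -w;
}

static double cap_lp(double x) {
  const double c = 37.5;
  return x > c ? c : (x < -c ? -c : x);
}

struct EvalPoint {
  double post;
  vec mean;
  mat chR;     // upper Cholesky of the proposal precision
  double ldet;
};

// target log-density (probit log-likelihood + normal prior) together with
// the Newton proposal built from the observed information
static EvalPoint eval_point(const mat& Gk, const vec& off, const vec& s,
                            const vec& tk, double prior_var) {
  int n = Gk.n_rows, d = Gk.n_cols;
  vec lp = off + Gk * tk;
  double post = -0.5 * dot(tk, tk) / prior_var;
  vec zeta(n), wgt(n);
  for (int r = 0; r < n; ++r) {
    double x = cap_lp(s[r] * lp[r]);
    double lF = R::pnorm(x, 0.0, 1.0, 1, 1);
    double z = std::exp(R::dnorm(x, 0.0, 1.0, 1) - lF);
    post += lF;
    zeta[r] = s[r] * z;
    double w = z * (z + x);
    wgt[r] = w > 0 ? std::sqrt(w) : 0.0;
  }
  mat Gw = Gk.each_col() % wgt;
  mat Pm = Gw.t() * Gw;
  Pm.diag() += 1.0 / prior_var;
  vec grad = Gk.t() * zeta - tk / prior_var;
  EvalPoint ep;
  ep.chR = chol(Pm);
  ep.ldet = accu(log(ep.chR.diag()));
  ep.mean = tk + solve(trimatu(ep.chR),
                       solve(trimatl(ep.chR.t()), grad));
  ep.post = post;
  return ep;
}

static double qdens(const vec& x, const EvalPoint& p) {
  vec r = p.chR * (x - p.mean);
  return p.ldet - 0.5 * dot(r, r);
}

// Metropolis-Hastings update of one hazard block given the random effects
static vec mh_block(const mat& Gk, const vec& off, const vec& s, vec tk,
                    double prior_var, int n_steps) {
  int d = Gk.n_cols;
  EvalPoint pc = eval_point(Gk, off, s, tk, prior_var);
  for (int step = 0; step < n_steps; ++step) {
    vec z(d);
    for (int j = 0; j < d; ++j) z[j] = R::norm_rand();
    vec tks = pc.mean + solve(trimatu(pc.chR), z);
    EvalPoint ps = eval_point(Gk, off, s, tks, prior_var);
    double la = ps.post - pc.post + qdens(tk, ps) - qdens(tks, pc);
    if (std::isfinite(la) && std::log(R::unif_rand()) < la) {
      tk = tks;
      pc = ps;
    }
  }
  return tk;
}

// conjugate draw of a probit block given its truncated-normal latents;
// composed with the collapsed MH update this adds a diffusive component
// that cannot be trapped by the MH proposal's locality
static vec da_block(const mat& Gk, const vec& off, const vec& w, vec tk,
                    double prior_var) {
  int d = Gk.n_cols;
  mat prec = Gk.t() * Gk;
  prec.diag() += 1.0 / prior_var;
  vec rhs = Gk.t() * (w - off);
  mat R = chol(prec);
  vec m = solve(trimatu(R), solve(trimatl(R.t()), rhs));
  vec z(d);
  for (int j = 0; j < d; ++j) z[j] = R::norm_rand();
  return m + solve(trimatu(R), z);
}

static vec draw_mvn_prec(const vec& rhs, mat prec) {
  mat R = chol(prec);
  vec m = solve(trimatu(R), solve(trimatl(R.t()), rhs));
  vec z(rhs.n_elem);
  for (uword j = 0; j < rhs.n_elem; ++j) z[j] = R::norm_rand();
  return m + solve(trimatu(R), z);
}

// build Sigma from the modified Cholesky parameters
static mat sigma_from(const vec& lambda, const vec& innov) {
  int q = innov.n_elem;
  mat L = eye(q, q);
  int pos = 0;
  for (int k = 1; k < q; ++k)
    for (int l = 0; l < k; ++l) L(k, l) = -lambda[pos++];
  mat Linv = inv(trimatl(L));
  return Linv * diagmat(innov) * Linv.t();
}

// [[Rcpp::export(name = ".gibbs_run_cpp")]]
Rcpp::List gibbs_run_cpp(
    const arma::mat& Xl, const arma::mat& Zl, const arma::vec& yv,
    const arma::ivec& lidx,
    const arma::mat& XD, const arma::ivec& idxD, const arma::ivec& eD,
    const arma::mat& XS, const arma::ivec& idxS, const arma::ivec& eS,
    const arma::mat& WD, const arma::mat& WS,
    int N, Rcpp::List prior, Rcpp::List init, Rcpp::List fixed,
    int n_iter, int warmup, int thin, int mh_steps, bool store_b) {

  Rcpp::RNGScope scope;
  const double v_beta = prior["beta_var"], v_lambda = prior["lambda_var"],
    v_assoc = prior["assoc_var"];
  const vec ig_eps = prior["sigma2_eps_ig"], ig_in = prior["innov_ig"];

  vec beta = init["beta"], thD = init["thD"], thS = init["thS"];
  double s2e = init["s2e"];
  vec lambda = init["lambda"], innov = init["innov"];
  mat B = init["B"];

  const bool fxGD = fixed["gamma_D"], fxGS = fixed["gamma_S"],
    fxS2 = fixed["sigma2_eps"], fxLam = fixed["lambda"],
    fxInn = fixed["innov"];

  const int p = beta.n_elem, pD = XD.n_cols, pS = XS.n_cols,
    qD = WD.n_rows, qS = WS.n_rows, q = WD.n_cols;
  const int nlong = yv.n_elem, nD = eD.n_elem, nS = eS.n_elem;

  // per-patient constants
  cube ZtZ(q, q, N, fill::zeros);
  vec cntD(N, fill::zeros), cntS(N, fill::zeros);
  for (int r = 0; r < nlong; ++r)
    ZtZ.slice(lidx[r] - 1) += Zl.row(r).t() * Zl.row(r);
  for (int r = 0; r < nD; ++r) cntD[idxD[r] - 1] += 1.0;
  for (int r = 0; r < nS; ++r) cntS[idxS[r] - 1] += 1.0;
  mat XtX = Xl.t() * Xl;

  vec sD(nD), sS(nS);
  for (int r = 0; r < nD; ++r) sD[r] = 1.0 - 2.0 * eD[r];
  for (int r = 0; r < nS; ++r) sS[r] = 1.0 - 2.0 * eS[r];

  mat Sigma = sigma_from(lambda, innov);
  int n_keep = (n_iter - warmup) / thin;
  int npar = p + pD + qD + pS + qS + 1 + lambda.n_elem + q;
  mat out(n_keep, npar);
  mat Bsum(N, q, fill::zeros);
  int row_out = 0;

  vec wD(nD), wS(nS);

  for (int it = 1; it <= n_iter; ++it) {
    // --- hazard blocks: collapsed MH given B -------------------------
    mat BWD = B * WD.t();     // N x qD
    mat BWS = B * WS.t();
    {
      mat G(nD, pD + qD);
      G.cols(0, pD - 1) = XD;
      for (int r = 0; r < nD; ++r)
        G(r, span(pD, pD + qD - 1)) = BWD.row(idxD[r] - 1);
      if (nD > 0) {
        if (fxGD) {
          vec off = G.cols(pD, pD + qD - 1) *
            thD.subvec(pD, pD + qD - 1);
          thD.subvec(0, pD - 1) = mh_block(G.cols(0, pD - 1), off, sD,
                                           thD.subvec(0, pD - 1),
                                           v_assoc, mh_steps);
        } else {
          vec off(nD, fill::zeros);
          thD = mh_block(G, off, sD, thD, v_assoc, mh_steps);
        }
      } else {
        for (int j = 0; j < pD + (fxGD ? 0 : qD); ++j)
          thD[j] = R::norm_rand() * std::sqrt(v_assoc);
      }
      // --- latent truncated normals for the dropout rows ---
      vec lpD = G * thD;
      for (int r = 0; r < nD; ++r)
        wD[r] = rtnorm01(lpD[r], eD[r] == 0);
      if (nD > 0) {          // diffusive conjugate refresh of the block
        if (fxGD) {
          vec off = G.cols(pD, pD + qD - 1) *
            thD.subvec(pD, pD + qD - 1);
          thD.subvec(0, pD - 1) = da_block(G.cols(0, pD - 1), off, wD,
                                           thD.subvec(0, pD - 1), v_assoc);
        } else {
          vec off(nD, fill::zeros);
          thD = da_block(G, off, wD, thD, v_assoc);
        }
        vec lp2 = G * thD;   // refresh latents under the new block
        for (int r = 0; r < nD; ++r)
          wD[r] = rtnorm01(lp2[r], eD[r] == 0);
      }
    }
    {
      mat G(nS, pS + qS);
      G.cols(0, pS - 1) = XS;
      for (int r = 0; r < nS; ++r)
        G(r, span(pS, pS + qS - 1)) = BWS.row(idxS[r] - 1);
      if (nS > 0) {
        if (fxGS) {
          vec off = G.cols(pS, pS + qS - 1) *
            thS.subvec(pS, pS + qS - 1);
          thS.subvec(0, pS - 1) = mh_block(G.cols(0, pS - 1), off, sS,
                                           thS.subvec(0, pS - 1),
                                           v_assoc, mh_steps);
        } else {
          vec off(nS, fill::zeros);
          thS = mh_block(G, off, sS, thS, v_assoc, mh_steps);
        }
      } else {
        for (int j = 0; j < pS + (fxGS ? 0 : qS); ++j)
          thS[j] = R::norm_rand() * std::sqrt(v_assoc);
      }
      vec lpS = G * thS;
      for (int r = 0; r < nS; ++r)
        wS[r] = rtnorm01(lpS[r], eS[r] == 0);
      if (nS > 0) {
        if (fxGS) {
          vec off = G.cols(pS, pS + qS - 1) *
            thS.subvec(pS, pS + qS - 1);
          thS.subvec(0, pS - 1) = da_block(G.cols(0, pS - 1), off, wS,
                                           thS.subvec(0, pS - 1), v_assoc);
        } else {
          vec off(nS, fill::zeros);
          thS = da_block(G, off, wS, thS, v_assoc);
        }
        vec lp2 = G * thS;
        for (int r = 0; r < nS; ++r)
          wS[r] = rtnorm01(lp2[r], eS[r] == 0);
      }
    }

    // --- random effects ---------------------------------------------
    vec cDv = WD.t() * thD.subvec(pD, pD + qD - 1);
    vec cSv = WS.t() * thS.subvec(pS, pS + qS - 1);
    if (N > 0) {
      mat Sinv = inv_sympd(Sigma);
      vec resid = yv - Xl * beta;
      mat Zres(N, q, fill::zeros);
      for (int r = 0; r < nlong; ++r)
        Zres.row(lidx[r] - 1) += Zl.row(r) * resid[r];
      vec sumD(N, fill::zeros), sumS(N, fill::zeros);
      vec XDa = XD * thD.subvec(0, pD - 1);
      vec XSa = XS * thS.subvec(0, pS - 1);
      for (int r = 0; r < nD; ++r)
        sumD[idxD[r] - 1] += wD[r] - XDa[r];
      for (int r = 0; r < nS; ++r)
        sumS[idxS[r] - 1] += wS[r] - XSa[r];
      mat ccD = cDv * cDv.t(), ccS = cSv * cSv.t();
      if (q == 2) {
        // closed-form 2x2 precision inverse and Cholesky, no LAPACK
        const double s11 = Sinv(0, 0), s12 = Sinv(0, 1), s22 = Sinv(1, 1);
        for (int i = 0; i < N; ++i) {
          double P11 = s11 + ZtZ(0, 0, i) / s2e +
            cntD[i] * ccD(0, 0) + cntS[i] * ccS(0, 0);
          double P12 = s12 + ZtZ(0, 1, i) / s2e +
            cntD[i] * ccD(0, 1) + cntS[i] * ccS(0, 1);
          double P22 = s22 + ZtZ(1, 1, i) / s2e +
            cntD[i] * ccD(1, 1) + cntS[i] * ccS(1, 1);
          double m1 = Zres(i, 0) / s2e + cDv[0] * sumD[i] + cSv[0] * sumS[i];
          double m2 = Zres(i, 1) / s2e + cDv[1] * sumD[i] + cSv[1] * sumS[i];
          double det = P11 * P22 - P12 * P12;
          double V11 = P22 / det, V22 = P11 / det, V12 = -P12 / det;
          double mu1 = V11 * m1 + V12 * m2;
          double mu2 = V12 * m1 + V22 * m2;
          double l11 = std::sqrt(V11), l21 = V12 / l11;
          double l22 = std::sqrt(std::max(V22 - l21 * l21, 0.0));
          double e1 = R::norm_rand(), e2 = R::norm_rand();
          B(i, 0) = mu1 + l11 * e1;
          B(i, 1) = mu2 + l21 * e1 + l22 * e2;
        }
      } else {
        for (int i = 0; i < N; ++i) {
          mat P = Sinv + ZtZ.slice(i) / s2e + cntD[i] * ccD + cntS[i] * ccS;
          vec m = Zres.row(i).t() / s2e + cDv * sumD[i] + cSv * sumS[i];
          B.row(i) = draw_mvn_prec(m, P).t();
        }
      }
    }

    // --- fixed effects ----------------------------------------------
    vec zb(nlong);
    for (int r = 0; r < nlong; ++r)
      zb[r] = dot(Zl.row(r), B.row(lidx[r] - 1));
    mat precB = XtX / s2e;
    precB.diag() += 1.0 / v_beta;
    beta = draw_mvn_prec(Xl.t() * (yv - zb) / s2e, precB);

    // --- residual variance ------------------------------------------
    if (!fxS2) {
      vec r2 = yv - Xl * beta - zb;
      double ssq = dot(r2, r2);
      s2e = 1.0 / R::rgamma(ig_eps[0] + nlong / 2.0,
                            1.0 / (ig_eps[1] + ssq / 2.0));
    }

    // --- random-effects covariance via sequential regressions -------
    if (!fxInn)
      innov[0] = 1.0 / R::rgamma(ig_in[0] + N / 2.0,
                                 1.0 / (ig_in[1] +
                                        dot(B.col(0), B.col(0)) / 2.0));
    int pos = 0;
    for (int k = 1; k < q; ++k) {
      mat Xk = B.cols(0, k - 1);
      vec lam_k(k);
      if (!fxLam) {
        mat prec = Xk.t() * Xk / innov[k];
        prec.diag() += 1.0 / v_lambda;
        lam_k = draw_mvn_prec(Xk.t() * B.col(k) / innov[k], prec);
        for (int l = 0; l < k; ++l) lambda[pos + l] = lam_k[l];
      } else {
        for (int l = 0; l < k; ++l) lam_k[l] = lambda[pos + l];
      }
      if (!fxInn) {
        vec rr = B.col(k) - Xk * lam_k;
        innov[k] = 1.0 / R::rgamma(ig_in[0] + N / 2.0,
                                   1.0 / (ig_in[1] + dot(rr, rr) / 2.0));
      }
      pos += k;
    }
    Sigma = sigma_from(lambda, innov);

    if (it > warmup && (it - warmup) % thin == 0) {
      int c = 0;
      for (int j = 0; j < p; ++j) out(row_out, c++) = beta[j];
      for (int j = 0; j < pD + qD; ++j) out(row_out, c++) = thD[j];
      for (int j = 0; j < pS + qS; ++j) out(row_out, c++) = thS[j];
      out(row_out, c++) = s2e;
      for (uword j = 0; j < lambda.n_elem; ++j)
        out(row_out, c++) = lambda[j];
      for (int j = 0; j < q; ++j) out(row_out, c++) = innov[j];
      if (store_b) Bsum += B;
      ++row_out;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("draws") = out,
    Rcpp::Named("b_mean") = store_b && row_out > 0 ?
      Rcpp::wrap(mat(Bsum / row_out)) : R_NilValue);
}
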