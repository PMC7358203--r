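#include <Rcpp.h>
using namespace Rcpp;

// Per-gene sampler for the hierarchical expression/splicing model:
//
//   beta  ~ Normal(0, 5)                     (variance 5, log2-cpm scale)
//   beta0 ~ Normal(mu1, 5)
//   gene obs       y_s   ~ Normal(beta0 + beta * case_s, vg_s)
//   p, alpha ~ Dirichlet(1, ..., 1)
//   centered iso obs  d_is = tr_is - y_gs ~ Normal(log2(f_i(s)), viso_is)
//     with f_i = p_i for control samples and f_i = p'_i for case samples,
//     p' the Aitchison perturbation of p by alpha.
//
// The model factorizes: (beta0, beta) have a bivariate normal posterior
// given the gene-level observations alone and are drawn exactly (iid);
// p and alpha are updated by random-walk Metropolis on additive-log-ratio
// (ALR) coordinates with step sizes adapted during warmup.  All randomness
// comes from R's RNG, so set.seed() makes runs reproducible.

static const double LOG2 = 0.6931471805599453;
static const double PRIOR_VAR = 5.0;

// log2 of the perturbed fractions p' from log-scale p and alpha
static void perturb_log2(const std::vector<double> &logp,
                         const std::vector<double> &loga,
                         std::vector<double> &out) {
    int T = logp.size();
    double mx = R_NegInf;
    for (int i = 0; i < T; ++i) {
        out[i] = logp[i] + loga[i];
        if (out[i] > mx) mx = out[i];
    }
    double s = 0.0;
    for (int i = 0; i < T; ++i) s += std::exp(out[i] - mx);
    double logZ = mx + std::log(s);
    for (int i = 0; i < T; ++i) out[i] = (out[i] - logZ) / LOG2;
}

// composition-block log likelihood given log2 fractions
static double iso_loglik(const NumericMatrix &d, const NumericMatrix &w,
                         const LogicalVector &isCase,
                         const std::vector<double> &l2ctrl,
                         const std::vector<double> &l2case) {
    int T = d.nrow(), n = d.ncol();
    double ll = 0.0;
    for (int s = 0; s < n; ++s) {
        const std::vector<double> &l2 = isCase[s] ? l2case : l2ctrl;
        for (int i = 0; i < T; ++i) {
            double r = d(i, s) - l2[i];
            ll -= 0.5 * r * r * w(i, s);
        }
    }
    return ll;
}

// normalize ALR coordinates in place to log fractions; returns the ALR
// Jacobian term sum(log f_i)
static double alr_to_log(std::vector<double> &lf) {
    int T = lf.size();
    double mx = *std::max_element(lf.begin(), lf.end());
    double s = 0.0;
    for (int i = 0; i < T; ++i) s += std::exp(lf[i] - mx);
    double lz = mx + std::log(s);
    double jac = 0.0;
    for (int i = 0; i < T; ++i) {
        lf[i] -= lz;
        jac += lf[i];
    }
    return jac;
}

// [[Rcpp::export(name = ".geneSampler")]]
List gene_sampler(NumericVector yg, NumericVector vg,
                  NumericMatrix dIso, NumericMatrix viso,
                  LogicalVector isCase, double mu1,
                  int warmup, int steps, int sweeps,
                  NumericVector pInit) {
    int n = yg.size();
    int T = dIso.nrow();
    bool hasIso = T >= 2;
    int D = steps - warmup;

    // exact bivariate normal posterior of (beta0, beta) from gene block
    double a11 = 1.0 / PRIOR_VAR, a12 = 0.0, a22 = 1.0 / PRIOR_VAR;
    double b1 = mu1 / PRIOR_VAR, b2 = 0.0;
    for (int s = 0; s < n; ++s) {
        double w = 1.0 / vg[s];
        a11 += w;
        b1 += w * yg[s];
        if (isCase[s]) {
            a12 += w; a22 += w;
            b2 += w * yg[s];
        }
    }
    double l11 = std::sqrt(a11);
    double l21 = a12 / l11;
    double l22 = std::sqrt(a22 - l21 * l21);
    double u1 = b1 / l11;
    double u2 = (b2 - l21 * u1) / l22;
    double mBeta = u2 / l22;
    double mBeta0 = (u1 - l21 * mBeta) / l11;

    NumericMatrix wi(T, dIso.ncol());
    if (hasIso)
        for (int s = 0; s < dIso.ncol(); ++s)
            for (int i = 0; i < T; ++i) wi(i, s) = 1.0 / viso(i, s);

    std::vector<double> logp(T), loga(T), l2ctrl(T), l2case(T);
    double jacP = 0.0, jacA = 0.0;
    if (hasIso) {
        for (int i = 0; i < T; ++i) {
            logp[i] = std::log(std::max(pInit[i], 1e-12));
            loga[i] = 0.0;
        }
        jacP = alr_to_log(logp);
        jacA = alr_to_log(loga);
        for (int i = 0; i < T; ++i) l2ctrl[i] = logp[i] / LOG2;
        perturb_log2(logp, loga, l2case);
    }

    NumericVector outB0(D), outB(D);
    NumericMatrix outP(hasIso ? D : 0, T), outA(hasIso ? D : 0, T);

    double stepP = 0.3, stepA = 0.3, stepS = 0.3;
    int accP = 0, accA = 0, accS = 0, tryAdapt = 0;
    int accPpost = 0, accApost = 0, tryPost = 0;
    std::vector<double> propLog(T), propLogA(T), propL2c(T), propL2k(T);
    // per-coordinate proposal scales, learned from the warmup chain
    // (Welford running variance of the ALR coordinates)
    std::vector<double> scP(T, 1.0), scA(T, 1.0);
    std::vector<double> mP(T, 0.0), vP(T, 0.0), mA(T, 0.0), vA(T, 0.0);
    long nW = 0;

    double curLik = hasIso
        ? iso_loglik(dIso, wi, isCase, l2ctrl, l2case) : 0.0;

    for (int it = 0; it < steps; ++it) {
        // exact draw of (beta0, beta): mean + L'^{-1} z
        double z1 = R::rnorm(0.0, 1.0), z2 = R::rnorm(0.0, 1.0);
        double d2 = z2 / l22;
        double d1 = (z1 - l21 * d2) / l11;
        double beta0 = mBeta0 + d1;
        double beta = mBeta + d2;

        if (hasIso) {
          for (int sw = 0; sw < sweeps; ++sw) {
            // MH update of p on ALR coordinates (last part is reference)
            ++tryAdapt;
            for (int i = 0; i < T - 1; ++i)
                propLog[i] = logp[i] - logp[T - 1] +
                    stepP * scP[i] * R::rnorm(0.0, 1.0);
            propLog[T - 1] = 0.0;
            double jacProp = alr_to_log(propLog);
            for (int i = 0; i < T; ++i) propL2c[i] = propLog[i] / LOG2;
            perturb_log2(propLog, loga, propL2k);
            double propLik = iso_loglik(dIso, wi, isCase, propL2c, propL2k);
            if (std::log(R::runif(0.0, 1.0)) <
                propLik + jacProp - curLik - jacP) {
                logp = propLog; l2ctrl = propL2c; l2case = propL2k;
                curLik = propLik; jacP = jacProp;
                ++accP;
                if (it >= warmup) ++accPpost;
            }

            // MH update of alpha
            for (int i = 0; i < T - 1; ++i)
                propLog[i] = loga[i] - loga[T - 1] +
                    stepA * scA[i] * R::rnorm(0.0, 1.0);
            propLog[T - 1] = 0.0;
            jacProp = alr_to_log(propLog);
            perturb_log2(logp, propLog, propL2k);
            double propLikA = iso_loglik(dIso, wi, isCase, l2ctrl, propL2k);
            if (std::log(R::runif(0.0, 1.0)) <
                propLikA + jacProp - curLik - jacA) {
                loga = propLog; l2case = propL2k;
                curLik = propLikA; jacA = jacProp;
                ++accA;
                if (it >= warmup) ++accApost;
            }

            // joint ridge move: the case fractions depend on p and alpha
            // only through p * alpha, leaving a poorly identified
            // direction (p_i up, alpha_i down); shift both ALR vectors
            // by opposite amounts, which keeps the perturbed case
            // fractions fixed and lets the chain travel along the ridge
            for (int i = 0; i < T - 1; ++i) {
                double eps = stepS *
                    std::sqrt(0.5 * (scP[i] * scP[i] + scA[i] * scA[i])) *
                    R::rnorm(0.0, 1.0);
                propLog[i] = logp[i] - logp[T - 1] + eps;
                propLogA[i] = loga[i] - loga[T - 1] - eps;
            }
            propLog[T - 1] = 0.0;
            propLogA[T - 1] = 0.0;
            jacProp = alr_to_log(propLog);
            double jacPropA = alr_to_log(propLogA);
            for (int i = 0; i < T; ++i) propL2c[i] = propLog[i] / LOG2;
            perturb_log2(propLog, propLogA, propL2k);
            double propLikS = iso_loglik(dIso, wi, isCase, propL2c,
                                         propL2k);
            if (std::log(R::runif(0.0, 1.0)) <
                propLikS + jacProp + jacPropA - curLik - jacP - jacA) {
                logp = propLog; loga = propLogA;
                l2ctrl = propL2c; l2case = propL2k;
                curLik = propLikS; jacP = jacProp; jacA = jacPropA;
                ++accS;
            }

          }
            // accumulate ALR coordinate variances during warmup and
            // refresh the per-coordinate scales every 200 iterations
            if (it < warmup) {
                ++nW;
                for (int i = 0; i < T - 1; ++i) {
                    double zp = logp[i] - logp[T - 1];
                    double za = loga[i] - loga[T - 1];
                    double dP = zp - mP[i];
                    mP[i] += dP / nW;
                    vP[i] += dP * (zp - mP[i]);
                    double dA = za - mA[i];
                    mA[i] += dA / nW;
                    vA[i] += dA * (za - mA[i]);
                }
                if (nW >= 200 && nW % 200 == 0) {
                    double gm = 0.0;
                    for (int i = 0; i < T - 1; ++i)
                        gm += 0.5 * std::log((vP[i] + vA[i]) / (2 * nW)
                                             + 1e-12);
                    gm = std::exp(gm / (T - 1));
                    for (int i = 0; i < T - 1; ++i) {
                        scP[i] = std::sqrt(vP[i] / nW + 1e-12) / gm;
                        scA[i] = std::sqrt(vA[i] / nW + 1e-12) / gm;
                        scP[i] = std::min(std::max(scP[i], 0.2), 5.0);
                        scA[i] = std::min(std::max(scA[i], 0.2), 5.0);
                    }
                }
            }
            // step-size adaptation, warmup only, blocks of 50
            if (it < warmup && tryAdapt >= 50) {
                stepP *= std::exp((double)accP / tryAdapt - 0.3);
                stepA *= std::exp((double)accA / tryAdapt - 0.3);
                stepS *= std::exp((double)accS / tryAdapt - 0.3);
                stepP = std::min(std::max(stepP, 1e-3), 10.0);
                stepA = std::min(std::max(stepA, 1e-3), 10.0);
                stepS = std::min(std::max(stepS, 1e-3), 10.0);
                accP = accA = accS = 0; tryAdapt = 0;
            }
        }

        if (it >= warmup) {
            ++tryPost;
            int d = it - warmup;
            outB0[d] = beta0;
            outB[d] = beta;
            if (hasIso) {
                double sp = 0.0, sa = 0.0;
                for (int i = 0; i < T; ++i) {
                    outP(d, i) = std::exp(logp[i]);
                    outA(d, i) = std::exp(loga[i]);
                    sp += outP(d, i); sa += outA(d, i);
                }
                for (int i = 0; i < T; ++i) {
                    outP(d, i) /= sp; outA(d, i) /= sa;
                }
            }
        }
    }

    List res = List::create(
        Named("beta0") = outB0,
        Named("beta") = outB,
        Named("accept_p") = (hasIso && tryPost)
            ? (double)accPpost / (tryPost * (double)sweeps) : NA_REAL,
        Named("accept_alpha") = (hasIso && tryPost)
            ? (double)accApost / (tryPost * (double)sweeps) : NA_REAL);
    if (hasIso) {
        res["p"] = outP;
        res["alpha"] = outA;
    }
    return res;
}
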