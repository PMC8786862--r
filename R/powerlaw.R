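## Discrete power-law fitting in the Clauset-Shalizi-Newman style:
## MLE exponent on the tail x >= xmin, xmin chosen by KS minimization,
## goodness of fit by semi-parametric bootstrap.

## generalized (Hurwitz) zeta: sum_{x=a}^{Inf} x^(-s), via a partial sum
## plus an Euler-Maclaurin tail; accurate to ~1e-12 for s > 1
hzeta <- function(s, a, terms = 512L) {
    xs <- seq.int(a, length.out = terms)
    m <- a + terms
    sum(exp(-s * log(xs))) +
        m^(1 - s) / (s - 1) + m^(-s) / 2 + s * m^(-s - 1) / 12
}

## model CDF (inclusive) of the discrete power law at integer x >= xmin
dpl_cdf <- function(x, alpha, xmin, z = hzeta(alpha, xmin)) {
    vapply(x, function(xi) 1 - hzeta(alpha, xi + 1) / z, numeric(1))
}

## MLE of alpha for the tail (all values >= xmin)
dpl_mle <- function(tail_vals, xmin) {
    slx <- sum(log(tail_vals))
    n <- length(tail_vals)
    nll <- function(s) n * log(hzeta(s, xmin)) + s * slx
    optimize(nll, interval = c(1.001, 25), tol = 1e-5)$minimum
}

## KS distance between empirical and model CDF, evaluated at the
## observed unique tail values (plfit convention)
dpl_ks <- function(tail_vals, alpha, xmin) {
    ## both CDFs are right-continuous steps jumping at the same integers,
    ## so the sup distance is attained at the inclusive values
    u <- sort(unique(tail_vals))
    cnt <- tabulate(factor(tail_vals, levels = u))
    emp <- cumsum(cnt) / length(tail_vals)
    max(abs(emp - dpl_cdf(u, alpha, xmin)))
}

## full fit: scan xmin candidates, MLE + KS for each, keep the minimum-KS
## candidate.  Returns list(alpha, xmin, ks, ntail).
plfit_discrete <- function(x, min_tail = 8L, max_candidates = 50L) {
    x <- x[is.finite(x) & x >= 1]
    x <- as.integer(round(x))
    if (length(x) < 2L) stop("need at least 2 positive observations")
    u <- sort(unique(x))
    if (length(u) < 2L)
        stop("degenerate fit: all observations are equal")
    ntail_at <- function(xm) sum(x >= xm)
    cand <- u[vapply(u, function(xm) {
        ntail_at(xm) >= min_tail && sum(u >= xm) >= 2L
    }, logical(1))]
    if (!length(cand)) cand <- u[1L]
    if (length(cand) > max_candidates)
        cand <- cand[unique(round(seq(1L, length(cand),
                                      length.out = max_candidates)))]
    best <- NULL
    for (xm in cand) {
        tl <- x[x >= xm]
        a <- dpl_mle(tl, xm)
        ks <- dpl_ks(tl, a, xm)
        if (is.null(best) || ks < best$ks)
            best <- list(alpha = a, xmin = xm, ks = ks, ntail = length(tl))
    }
    best
}

## sampler for the fitted discrete power law (inverse CDF with a
## continuous Pareto approximation beyond the tabulated cap)
make_dpl_sampler <- function(alpha, xmin, cap = 100000L) {
    z <- hzeta(alpha, xmin)
    xs <- seq.int(xmin, cap)
    cdf <- cumsum(exp(-alpha * log(xs))) / z
    function(n) {
        u <- runif(n)
        out <- xmin + findInterval(u, cdf)
        over <- out > cap
        if (any(over)) {
            pc <- cdf[length(cdf)]
            out[over] <- floor((cap + 0.5) *
                ((1 - pc) / (1 - u[over]))^(1 / (alpha - 1)))
        }
        out
    }
}

#' Fit a discrete power law to a degree sequence
#'
#' Maximum-likelihood fit of \eqn{P(x) \propto x^{-\alpha}} over the tail
#' \eqn{x \ge x_{min}}, with \eqn{x_{min}} selected by minimizing the
#' Kolmogorov-Smirnov distance between the empirical and fitted tails.
#' When \code{nBoot > 0}, goodness of fit is assessed by semi-parametric
#' bootstrap: each resample draws (with the observed tail fraction) from
#' the fitted model above \eqn{x_{min}} and uniformly from the observed
#' body below it, is refitted from scratch, and contributes its KS
#' statistic; \code{bootstrapP} is the fraction of resamples whose KS
#' exceeds the observed one.  Values below 1 are dropped; an all-equal
#' sequence is a degenerate-fit error.
#'
#' @param degrees integer vector (e.g. the degree sequence of a network).
#' @param nBoot bootstrap resamples, default 2500; 0 skips the bootstrap.
#' @param seed explicit RNG seed for the bootstrap.
#' @param minTail smallest tail size an \eqn{x_{min}} candidate may leave.
#' @param minTailFrac smallest fraction of the data an \eqn{x_{min}}
#'   candidate may leave in the tail (default 0.10).  An unrestricted scan
#'   can select a far-tail sliver of a clearly non-power-law distribution
#'   (a handful of support values fit any monotone model well), which
#'   makes the goodness-of-fit test powerless; bounding the scanned tail
#'   keeps the test able to reject.  Set to 0 for the unrestricted
#'   Clauset scan.
#' @param maxCandidates cap on the number of scanned \eqn{x_{min}}
#'   candidates (evenly thinned when exceeded).
#' @return a [PowerLawFit-class] with \code{kind = "mle_distribution"}.
#' @references Clauset, Shalizi and Newman (2009) SIAM Review 51:661-703.
#' @export
fitDegreeDistribution <- function(degrees, nBoot = 2500L, seed = 1L,
                                  minTail = 8L, minTailFrac = 0.10,
                                  maxCandidates = 50L) {
    ## non-positive degrees (isolated nodes) are excluded from the fit
    x <- degrees[is.finite(degrees) & degrees >= 1]
    if (length(x) < 50L)
        warning("fewer than 50 observations; exponent estimate is noisy")
    min_tail <- max(minTail, ceiling(minTailFrac * length(x)))
    obs <- plfit_discrete(x, min_tail, maxCandidates)
    pboot <- NA_real_
    nBoot <- as.integer(nBoot)
    if (nBoot > 0L) {
        body <- x[x < obs$xmin]
        ptail <- obs$ntail / length(x)
        sampler <- make_dpl_sampler(obs$alpha, obs$xmin)
        ks_boot <- with_explicit_seed(seed, {
            vapply(seq_len(nBoot), function(b) {
                nt <- stats::rbinom(1L, length(x), ptail)
                xb <- c(if (nt < length(x))
                            sample(body, length(x) - nt, replace = TRUE),
                        sampler(nt))
                fb <- tryCatch(plfit_discrete(xb, min_tail, maxCandidates),
                               error = function(e) NULL)
                if (is.null(fb)) NA_real_ else fb$ks
            }, numeric(1))
        })
        pboot <- mean(ks_boot >= obs$ks, na.rm = TRUE)
    }
    new("PowerLawFit",
        exponent = obs$alpha, sign = -1, xmin = as.numeric(obs$xmin),
        ks = obs$ks, bootstrapP = pboot, nBoot = max(nBoot, 0L),
        nTail = as.integer(obs$ntail), kind = "mle_distribution",
        seed = if (nBoot > 0L) as.integer(seed) else NA_integer_)
}

#' Fit a power-law exponent to a degree-indexed curve
#'
#' Weighted least-squares regression of \eqn{\log(y)} on \eqn{\log(k)}
#' (weights typically the per-degree node counts \eqn{n_k}); the exponent
#' is the slope magnitude, with the sign kept separately (a positive
#' neighborhood-connectivity slope diagnoses assortativity).  Points with
#' non-positive \eqn{k} or \eqn{y} are excluded; fewer than 3 surviving
#' distinct degrees is an error.  The fit is invariant to rescaling the
#' curve by a constant.
#'
#' @param k degrees.
#' @param values curve values at those degrees.
#' @param weights optional non-negative weights (default equal).
#' @return a [PowerLawFit-class] with \code{kind = "loglog_regression"};
#'   \code{ks} holds the weighted RMS log-residual.
#' @export
fitCurveExponent <- function(k, values, weights = NULL) {
    stopifnot(length(k) == length(values))
    if (is.null(weights)) weights <- rep(1, length(k))
    keep <- is.finite(k) & is.finite(values) & k > 0 & values > 0 &
        weights > 0
    k <- k[keep]; values <- values[keep]; weights <- weights[keep]
    if (length(unique(k)) < 3L)
        stop("need at least 3 distinct degrees with positive values")
    fit <- lm(log(values) ~ log(k), weights = weights)
    slope <- unname(coef(fit)[2L])
    res <- sqrt(sum(weights * fit$residuals^2) / sum(weights))
    new("PowerLawFit",
        exponent = abs(slope), sign = if (slope >= 0) 1 else -1,
        xmin = min(k), ks = res, bootstrapP = NA_real_, nBoot = 0L,
        nTail = length(k), kind = "loglog_regression", seed = NA_integer_)
}

#' Fit all six topology exponents of a network
#'
#' Computes node metrics and degree curves, then fits: \code{gamma} for
#' P(k) (discrete MLE by default, optionally log-log regression),
#' and weighted log-log regressions for C(k) (\code{alpha}), CN(k)
#' (\code{beta}), CC(k) (\code{delta}), CB(k) (\code{mu}) and CE(k)
#' (\code{tau}), weighted by the per-degree node counts.  Curves with too
#' few positive points yield a NULL entry (NA in [exponents()]) with a
#' warning.
#'
#' @param net igraph object, or NULL when \code{curves} is given.
#' @param curves optional precomputed [degreeCurves()] table.
#' @param gammaMethod \code{"mle"} (default) or \code{"regression"}.
#' @param nBoot bootstrap resamples for the gamma fit (0 = skip).
#' @param seed bootstrap seed.
#' @param degrees raw degree sequence; required for \code{"mle"} when
#'   \code{net} is NULL.
#' @return an [ExponentSet-class].
#' @export
fitAllExponents <- function(net = NULL, curves = NULL,
                            gammaMethod = c("mle", "regression"),
                            nBoot = 0L, seed = 1L, degrees = NULL) {
    gammaMethod <- match.arg(gammaMethod)
    if (is.null(curves)) {
        stopifnot(!is.null(net))
        curves <- degreeCurves(computeNodeMetrics(net))
    }
    if (is.null(degrees) && !is.null(net))
        degrees <- as.integer(igraph::degree(net))
    try_fit <- function(y) tryCatch(
        fitCurveExponent(curves$k, y, weights = curves$nK),
        error = function(e) { warning(conditionMessage(e)); NULL })
    gamma_fit <- if (gammaMethod == "mle") {
        if (is.null(degrees))
            stop("gammaMethod = 'mle' needs the raw degree sequence")
        tryCatch(fitDegreeDistribution(degrees, nBoot = nBoot, seed = seed),
                 error = function(e) { warning(conditionMessage(e)); NULL })
    } else try_fit(curves$Pk)
    new("ExponentSet", fits = list(
        gamma = gamma_fit, alpha = try_fit(curves$C),
        beta = try_fit(curves$CN), delta = try_fit(curves$CC),
        mu = try_fit(curves$CB), tau = try_fit(curves$CE)))
}

#' Classify a network from its fitted exponents
#'
#' Labels: \code{scale_free} when the degree-distribution fit passes the
#' bootstrap acceptance rule (p > 0.1) and its KS statistic does not
#' exceed \code{ksCap}; \code{hierarchical} when additionally the
#' clustering curve C(k) decays (negative slope); \code{assortative} /
#' \code{disassortative} from the sign of the neighborhood-connectivity
#' slope \code{beta}.
#'
#' @param es an [ExponentSet-class] whose gamma fit carries a bootstrap
#'   p-value.
#' @param pAccept bootstrap acceptance threshold, default 0.1.
#' @param ksCap cap on the accepted KS statistic, default 0.33.
#' @return character vector of labels (possibly empty).
#' @export
classifyNetwork <- function(es, pAccept = 0.1, ksCap = 0.33) {
    stopifnot(is(es, "ExponentSet"))
    labels <- character(0)
    g <- es@fits$gamma
    sf <- !is.null(g) && !is.na(g@bootstrapP) &&
        g@bootstrapP > pAccept && g@ks <= ksCap
    if (sf) {
        labels <- c(labels, "scale_free")
        a <- es@fits$alpha
        if (!is.null(a) && a@sign < 0)
            labels <- c(labels, "hierarchical")
    }
    b <- es@fits$beta
    if (!is.null(b))
        labels <- c(labels, if (b@sign > 0) "assortative" else "disassortative")
    labels
}
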