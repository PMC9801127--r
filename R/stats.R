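## Downstream numerics: Michaelis-Menten fitting, linear regression with
## r-squared, replicate group tests, and the methyl-transfer distance
## arithmetic from the structure model.

#' Fit the Michaelis-Menten equation by nonlinear least squares
#'
#' Fits \code{v = Vmax * S / (Km + S)} by Levenberg-Marquardt least
#' squares with positivity bounds.  Initialization: \code{Vmax0 = max(v)},
#' \code{Km0 =} the substrate concentration whose velocity is closest to
#' \code{Vmax0 / 2}.  Negative velocities are clipped to 0 with a warning.
#' No Lineweaver-Burk linearization is used anywhere (it biases the
#' estimates); the fit is nonlinear only.  Unidentifiable designs (e.g.
#' velocities flat across all concentrations, so only the saturated regime
#' was observed) and non-convergence are flagged rather than raised.
#'
#' @param data data.frame with columns \code{S} (substrate concentration,
#'   typically micromolar) and \code{v} (initial velocity); replicates are
#'   simply additional rows.
#' @return a [KineticFit-class].
#' @examples
#' S <- c(0.5, 1, 2, 5, 10, 20)
#' fit <- fitMichaelisMenten(data.frame(S = S, v = 0.003 * S / (4.6 + S)))
#' km(fit); vmax(fit)
#' @export
fitMichaelisMenten <- function(data) {
  stopifnot(all(c("S", "v") %in% names(data)))
  S <- as.numeric(data$S)
  v <- as.numeric(data$v)
  if (length(unique(S)) < 3L)
    stop("need at least 3 distinct substrate concentrations", call. = FALSE)
  if (any(v < 0)) {
    warning("negative velocities clipped to 0 before fitting")
    v <- pmax(v, 0)
  }
  vmax0 <- max(v)
  km0 <- S[which.min(abs(v - vmax0 / 2))]
  flagged <- function(msg) new("KineticFit", km = NA_real_, vmax = NA_real_,
                               rss = NA_real_, converged = FALSE,
                               message = msg)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                      data = data.frame(S = S, v = v),
                      start = list(Vmax = vmax0, Km = max(km0, 1e-9)),
                      lower = c(Vmax = 1e-12, Km = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(flagged("nonlinear fit did not converge"))
  p <- coef(fit)
  rss <- sum(residuals(fit)^2)
  ## identifiability: Km at the box bound or with an enormous relative
  ## standard error means the design never left the saturated regime
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  if (p[["Km"]] <= 1e-9 ||
      (is.finite(se[["Km"]]) && se[["Km"]] > 10 * p[["Km"]]) ||
      !is.finite(se[["Km"]]))
    return(flagged("Km unidentifiable for this design"))
  new("KineticFit", km = unname(p[["Km"]]), vmax = unname(p[["Vmax"]]),
      rss = rss, converged = TRUE, message = "")
}

#' Simulate Michaelis-Menten initial-velocity data
#'
#' Generates \code{v = Vmax * S / (Km + S)} at the given concentrations
#' with multiplicative Gaussian noise (\code{v * (1 + N(0, cv))}) and
#' \code{nrep} replicates, the usual error model for initial-rate assays.
#'
#' @param S substrate concentrations.
#' @param km,vmax true parameters.
#' @param cv coefficient of variation of the noise (0 = noiseless).
#' @param nrep replicates per concentration.
#' @param seed RNG seed.
#' @return data.frame with columns \code{S}, \code{v}, \code{replicate}.
#' @export
simulateMichaelisMenten <- function(S, km, vmax, cv = 0, nrep = 1L,
                                    seed = 1L) {
  set.seed(seed)
  d <- expand.grid(replicate = seq_len(nrep), S = S)[, c("S", "replicate")]
  mu <- vmax * d$S / (km + d$S)
  d$v <- mu * (1 + if (cv > 0) rnorm(nrow(d), 0, cv) else 0)
  d
}

#' Ordinary least-squares line with r-squared
#'
#' @param x,y numeric vectors of equal length (at least 2; x must vary).
#' @return list with \code{slope}, \code{intercept}, \code{rSquared}.
#' @examples
#' linearFitR2(1:4, 2 * (1:4) + 1)$rSquared  # 1
#' @export
linearFitR2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2", call. = FALSE)
  if (stats::var(x) == 0) stop("x must not be constant", call. = FALSE)
  f <- lm(y ~ x)
  ssRes <- sum(residuals(f)^2)
  ssTot <- sum((y - mean(y))^2)
  list(slope = unname(coef(f)[2L]), intercept = unname(coef(f)[1L]),
       rSquared = if (ssTot == 0) 1 else 1 - ssRes / ssTot)
}

#' Welch two-sample comparison of replicate rates
#'
#' Two-sided Welch t-test, the standard choice for small replicate groups
#' with unequal variances.  Degenerate input (zero variance in both
#' groups) returns p = 1 when the means agree and p = 0 otherwise.
#'
#' @param a,b numeric vectors of replicate rates (length >= 2 each).
#' @return two-sided p-value.
#' @export
compareGroups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 values per group", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  t.test(a, b, var.equal = FALSE)$p.value
}

#' Distance from the target N1 atom to the donor methyl group
#'
#' In the docked enzyme-tRNA model the catalytic geometry is summarized by
#' two measured distances: N1 of the target adenosine to the sulfur of the
#' bound AdoHcy, and the sulfur-to-methyl carbon bond length in AdoMet.
#' The N1-to-methyl distance is their difference, the gap a conformational
#' change must close for methyl transfer.
#'
#' @param n1ToSulfur N1-to-sulfur distance in Angstroms.
#' @param sulfurToMethyl S-CH3 bond length in Angstroms.
#' @return estimated N1-to-methyl-carbon distance in Angstroms.
#' @examples
#' methylTransferDistance(9.4, 1.8)  # ~7.6
#' @export
methylTransferDistance <- function(n1ToSulfur, sulfurToMethyl) {
  stopifnot(n1ToSulfur >= sulfurToMethyl)
  n1ToSulfur - sulfurToMethyl
}
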