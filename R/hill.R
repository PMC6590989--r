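## Hill-model dose-response analysis.
##
## Model: deltaCa(c) = Max * c^H / (c^H + EC50^H), fitted to pooled
## per-cell responses by nonlinear least squares with positivity enforced
## through log-parameterization.

#' Hill equation prediction
#'
#' Evaluates Max * c^H / (c^H + EC50^H), computed in log space as
#' Max / (1 + exp(H * (log(EC50) - log(c)))) for numerical stability at
#' extreme concentrations.
#'
#' @param concentration agonist concentration(s), same units as EC50
#'   (conventionally uM); must be positive.
#' @param max maximal response (Max), e.g. peak intracellular Ca2+
#'   increase in uM.
#' @param ec50 half-effective concentration.
#' @param hs Hill coefficient.
#' @return predicted response(s).
#' @examples
#' predictHill(11.8, max = 0.79, ec50 = 11.8, hs = 2)  # = Max/2
#' @export
predictHill <- function(concentration, max, ec50, hs) {
  if (any(concentration <= 0)) stop("concentrations must be positive")
  if (max <= 0 || ec50 <= 0 || hs <= 0)
    stop("Hill parameters must be positive")
  max / (1 + exp(hs * (log(ec50) - log(concentration))))
}

#' Fit the Hill model to per-cell responses
#'
#' Nonlinear least squares on all cells pooled (or on per-concentration
#' means).  Initialization: Max from the largest per-concentration mean,
#' EC50 by log-interpolating the half-maximal concentration, H_S = 1.
#' Positivity is enforced by fitting log(Max), log(EC50) and log(H_S);
#' H_S is bounded to [0.3, 10].  Non-convergence is flagged, never silent.
#'
#' @param responses data.frame with columns \code{concentration} and
#'   \code{delta_ca} (one row per cell).
#' @param mode "pooled" (default) fits all cells; "means" fits
#'   per-concentration mean responses.
#' @return a \linkS4class{HillFit}.
#' @export
fitHill <- function(responses, mode = c("pooled", "means")) {
  mode <- match.arg(mode)
  stopifnot(all(c("concentration", "delta_ca") %in% names(responses)))
  if (any(responses$concentration <= 0)) stop("concentrations must be positive")
  if (any(!is.finite(responses$delta_ca))) stop("responses must be finite")
  concs <- sort(unique(responses$concentration))
  if (length(concs) < 3)
    stop("need at least 3 distinct concentrations (under-determined fit)")
  nCells <- nrow(responses)
  df <- if (mode == "means") {
    means <- tapply(responses$delta_ca, responses$concentration, mean)
    data.frame(concentration = as.numeric(names(means)),
               delta_ca = as.numeric(means))
  } else responses[, c("concentration", "delta_ca")]

  # initialization from the per-concentration mean curve
  mcurve <- tapply(responses$delta_ca, responses$concentration, mean)
  cm <- as.numeric(names(mcurve)); ym <- as.numeric(mcurve)
  maxInit <- max(ym)
  if (maxInit <= 0) maxInit <- max(abs(ym)) + 1e-6
  half <- maxInit / 2
  above <- which(ym >= half)
  ec50Init <- if (length(above) && min(above) > 1) {
    i <- min(above)   # log-interpolate between the bracketing concentrations
    f <- (half - ym[i - 1]) / (ym[i] - ym[i - 1])
    exp(log(cm[i - 1]) + f * (log(cm[i]) - log(cm[i - 1])))
  } else stats::median(cm)

  start <- c(lmax = log(maxInit), lec50 = log(ec50Init), lhs = 0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      delta_ca ~ exp(lmax) / (1 + exp(exp(lhs) * (lec50 - log(concentration)))),
      data = df, start = as.list(start),
      lower = c(-Inf, -Inf, log(0.3)), upper = c(Inf, Inf, log(10)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new("HillFit",
               estimates = c(Max = NA_real_, EC50 = NA_real_, H_S = NA_real_),
               se = c(Max = NA_real_, EC50 = NA_real_, H_S = NA_real_),
               residualSd = NA_real_, nCells = as.integer(nCells),
               converged = FALSE, diagnostics = conditionMessage(fit),
               data = responses))
  }
  cf <- stats::coef(fit)
  est <- c(Max = exp(cf[["lmax"]]), EC50 = exp(cf[["lec50"]]),
           H_S = exp(cf[["lhs"]]))
  se <- tryCatch({
    s <- sqrt(diag(stats::vcov(fit)))
    c(Max = est[["Max"]] * s[["lmax"]], EC50 = est[["EC50"]] * s[["lec50"]],
      H_S = est[["H_S"]] * s[["lhs"]])   # delta method from the log scale
  }, error = function(e) c(Max = NA_real_, EC50 = NA_real_, H_S = NA_real_))
  new("HillFit", estimates = est, se = se,
      residualSd = stats::sd(stats::residuals(fit)),
      nCells = as.integer(nCells), converged = TRUE, diagnostics = "",
      data = responses)
}

#' Compare two dose-response conditions
#'
#' Reports the EC50 fold change (treated / control) and the Max ratio
#' (treated / control) with percentile bootstrap intervals obtained by
#' resampling cells within each condition (stratified by concentration so
#' every dose stays represented) and refitting.
#'
#' @param fitControl,fitTreated converged \linkS4class{HillFit}s (the raw
#'   cells travel inside the fit objects).
#' @param B number of bootstrap resamples (default 200).
#' @param seed RNG seed.
#' @param level confidence level for the percentile interval (default 0.95).
#' @return list with ec50_fold_change, max_ratio, their intervals
#'   (\code{ec50_ci}, \code{max_ci}), bootstrap failure rate, and a
#'   \code{flagged} field set when more than 20\% of resamples failed.
#' @export
compareConditions <- function(fitControl, fitTreated, B = 200L, seed = 1L,
                              level = 0.95) {
  if (!fitControl@converged || !fitTreated@converged)
    stop("both fits must have converged")
  ec50FC <- fitTreated@estimates[["EC50"]] / fitControl@estimates[["EC50"]]
  maxRatio <- fitTreated@estimates[["Max"]] / fitControl@estimates[["Max"]]

  resample <- function(d) {
    idx <- unlist(lapply(split(seq_len(nrow(d)), d$concentration),
                         function(i) sample(i, length(i), replace = TRUE)),
                  use.names = FALSE)
    d[idx, , drop = FALSE]
  }
  set.seed(seed)
  fc <- mr <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    fb <- tryCatch(fitHill(resample(fitControl@data)), error = function(e) NULL)
    ft <- tryCatch(fitHill(resample(fitTreated@data)), error = function(e) NULL)
    if (!is.null(fb) && !is.null(ft) && fb@converged && ft@converged) {
      fc[b] <- ft@estimates[["EC50"]] / fb@estimates[["EC50"]]
      mr[b] <- ft@estimates[["Max"]] / fb@estimates[["Max"]]
    }
  }
  failRate <- mean(is.na(fc))
  a <- (1 - level) / 2
  list(ec50_fold_change = ec50FC,
       max_ratio = maxRatio,
       ec50_ci = unname(stats::quantile(fc, c(a, 1 - a), na.rm = TRUE)),
       max_ci = unname(stats::quantile(mr, c(a, 1 - a), na.rm = TRUE)),
       B = B, bootstrap_failure_rate = failRate,
       flagged = failRate > 0.2)
}

#' Classify cholesterol-depletion sensitivity from a condition comparison
#'
#' A condition pair is called "sensitive" when the bootstrap interval of
#' the EC50 fold change excludes 1 (the depletion changed the channel's
#' agonist sensitivity) and "insensitive" otherwise, mirroring the
#' wild-type-sensitive versus CRAC-mutant-insensitive dichotomy.
#'
#' @param comparison result of [compareConditions()].
#' @return "sensitive" or "insensitive".
#' @export
classifyMcdSensitivity <- function(comparison) {
  ci <- comparison$ec50_ci
  if (any(!is.finite(ci))) stop("comparison lacks a finite bootstrap interval")
  if (ci[1] > 1 || ci[2] < 1) "sensitive" else "insensitive"
}

#' Read per-cell dose-response tables
#'
#' CSV with columns genotype, condition, concentration_uM, delta_ca_uM (the
#' two metadata columns optional).
#'
#' @param file CSV path.
#' @return data.frame with concentration, delta_ca, condition, genotype.
#' @export
readDoseCSV <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  out <- data.frame(concentration = df$concentration_uM,
                    delta_ca = df$delta_ca_uM)
  out$condition <- if (is.null(df$condition)) "control" else df$condition
  out$genotype <- if (is.null(df$genotype)) "WT" else df$genotype
  out
}
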