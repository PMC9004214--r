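#' Closed-form crude odds ratios from a contingency table
#'
#' For a levels-by-stages table of counts, the crude odds ratio of level `l`
#' (against the reference level) for stage `s` (against the reference stage)
#' is the cross-product ratio
#' `OR = (n[l, s] * n[ref, ref_stage]) / (n[l, ref_stage] * n[ref, s])`,
#' with Wald confidence interval
#' `exp(log OR +/- z * sqrt(1/n[l,s] + 1/n[ref,ref_stage] + 1/n[l,ref_stage] + 1/n[ref,s]))`.
#' This serves as the independent oracle for the fitted multinomial model: a
#' single-categorical-covariate fit is saturated and must reproduce these
#' ratios.
#'
#' @param counts numeric matrix of nonnegative counts, levels in rows and
#'   stages in columns, with dimnames.
#' @param ref_level row name of the reference covariate level (default first
#'   row).
#' @param ref_stage column name of the reference stage (default first column).
#' @param alpha significance level for the confidence interval (default 0.05).
#' @return An OR table: one row per (non-reference level, non-reference
#'   stage) with `level`, `stage`, `or`, `ci_low`, `ci_high`, `mode =
#'   "crude"`, `n`, and a `note` flagging zero cells (no continuity
#'   correction is applied silently).
#' @export
#' @examples
#' cnt <- rbind(M = c(3833, 4535, 3331, 8255), F = c(2227, 2707, 2080, 5485))
#' colnames(cnt) <- c("LT_90", "D90_365", "Y1_2", "GT_2Y")
#' crude_or_from_counts(cnt)
crude_or_from_counts <- function(counts, ref_level = rownames(counts)[1],
                                 ref_stage = colnames(counts)[1], alpha = 0.05) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have level row names and stage column names", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2)
  levels_ <- setdiff(rownames(counts), ref_level)
  stages_ <- setdiff(colnames(counts), ref_stage)
  rows <- tidyr::expand_grid(level = levels_, stage = stages_)
  res <- purrr::pmap(rows, function(level, stage) {
    cells <- c(counts[level, stage], counts[ref_level, ref_stage],
               counts[level, ref_stage], counts[ref_level, stage])
    or <- (cells[1] * cells[2]) / (cells[3] * cells[4])
    se <- sqrt(sum(1 / cells))
    note <- if (any(cells == 0)) "zero cell: OR/CI undefined without correction" else NA_character_
    tibble::tibble(level = level, stage = stage, or = or,
                   ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
                   mode = "crude", n = sum(counts), note = note)
  })
  purrr::list_rbind(res)
}

#' Newton fitter for the baseline-category multinomial logit
#'
#' Maximises the multinomial log-likelihood
#' `sum_i [ eta_{i, y_i} - log(1 + sum_k exp(eta_{ik})) ]`, `eta_k = X b_k`,
#' by full Newton-Raphson with step-halving, so the log-likelihood never
#' decreases across iterations. Convergence is declared when the relative
#' log-likelihood change falls below `tol`. No penalty is applied; quasi- or
#' complete separation shows up as non-convergence or a singular Hessian and
#' is surfaced in the `converged`/`message` fields, never silently clipped.
#'
#' @param X model matrix (n x p) including the intercept column.
#' @param y factor of K outcome stages; the first level is the reference.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Newton iteration cap (default 100).
#' @return List: `coef` (p x K-1 matrix), `vcov` of the stacked coefficients,
#'   `loglik`, `loglik_trace`, `converged`, `message`, `n`, `iter`.
#' @keywords internal
multinom_newton <- function(X, y, tol = 1e-8, max_iter = 100L) {
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  if (K < 2) stop("outcome must have at least 2 observed stages", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  Y <- matrix(0, n, K - 1)
  yi <- as.integer(y)
  for (k in 2:K) Y[yi == k, k - 1] <- 1

  B <- matrix(0, p, K - 1)
  loglik <- function(B) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    sum(rowSums(Y * eta)) - sum(m + log(exp(-m) + rowSums(exp(eta - m))))
  }
  ll <- loglik(B)
  trace <- ll
  converged <- FALSE
  msg <- "ok"
  iter <- 0L
  H <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    denom <- exp(-m) + rowSums(exp(eta - m))
    P <- exp(eta - m) / denom                     # n x (K-1) stage probabilities
    G <- crossprod(X, Y - P)                      # p x (K-1) score
    # Hessian blocks: H[k,l] = -X' diag(p_k (delta_kl - p_l)) X
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (k in seq_len(K - 1)) {
      for (l in seq_len(k)) {
        w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
        blk <- crossprod(X, X * w)
        ri <- (k - 1) * p + seq_len(p); ci <- (l - 1) * p + seq_len(p)
        H[ri, ci] <- blk
        H[ci, ri] <- t(blk)
      }
    }
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      msg <- "singular Hessian (possible separation)"
      break
    }
    # step-halving keeps the log-likelihood nondecreasing
    lambda <- 1
    repeat {
      B_new <- B + matrix(lambda * step, p, K - 1)
      ll_new <- loglik(B_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    if (lambda < 1e-10) {
      msg <- "step-halving failed to improve the log-likelihood"
      break
    }
    B <- B_new
    trace <- c(trace, ll_new)
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-12)
    ll <- ll_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
    if (max(abs(B)) > 30) {
      msg <- "diverging coefficients (possible separation)"
      break
    }
  }
  if (!converged && msg == "ok") msg <- "iteration limit reached"
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p * (K - 1), p * (K - 1)))
  dimnames(B) <- list(colnames(X), levels(y)[-1])
  list(coef = B, vcov = vcov, loglik = ll, loglik_trace = trace,
       converged = converged, message = msg, n = n, iter = iter,
       stage_levels = levels(y), term_names = colnames(X))
}

#' @keywords internal
or_rows_from_fit <- function(fit, covariate, alpha) {
  z <- stats::qnorm(1 - alpha / 2)
  p <- length(fit$term_names)
  stages <- fit$stage_levels[-1]
  rows <- list()
  for (k in seq_along(stages)) {
    for (j in seq_len(p)) {
      term <- fit$term_names[j]
      if (term == "(Intercept)") next
      b <- fit$coef[j, k]
      se <- sqrt(fit$vcov[(k - 1) * p + j, (k - 1) * p + j])
      rows[[length(rows) + 1]] <- tibble::tibble(
        covariate = covariate, level = term, stage = stages[k],
        or = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se))
    }
  }
  purrr::list_rbind(rows)
}

#' Fit crude or adjusted multinomial stage models
#'
#' Fits a baseline-category multinomial logit of cascade stage (reference
#' `LT_90`) on patient-level covariates and reports odds ratios
#' (`exp(coefficient)`) with Wald confidence intervals. In `crude` mode one
#' single-covariate model is fitted per covariate (the standard
#' epidemiological crude OR); in `adjusted` mode all covariates enter one
#' model. Rows with missing values in any modelled covariate are dropped
#' complete-case and counted in the `n_dropped` attribute.
#'
#' @param summaries patient-summary tibble with a `stage` factor column.
#' @param covariates character vector of covariate column names; factors give
#'   one OR per non-reference level, numeric columns one OR per unit.
#' @param mode `"crude"` or `"adjusted"`.
#' @param alpha significance level (default 0.05, i.e. 95% intervals).
#' @param ref_stage reference stage (default `"LT_90"`).
#' @param tol,max_iter passed to the Newton fitter.
#' @return OR table: `covariate`, `level` (model-matrix term), `stage`, `or`,
#'   `ci_low`, `ci_high`, `mode`, `n`, `converged`; fit diagnostics
#'   (log-likelihoods, messages, `n_dropped`) in attribute `fits`. A fit that
#'   fails to converge raises an error naming the covariate unless its rows
#'   are flagged `converged = FALSE` here.
#' @export
fit_multinomial <- function(summaries, covariates, mode = c("crude", "adjusted"),
                            alpha = 0.05, ref_stage = "LT_90",
                            tol = 1e-8, max_iter = 100L) {
  mode <- match.arg(mode)
  missing_cov <- setdiff(covariates, names(summaries))
  if (length(missing_cov) > 0) {
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  stage <- factor(summaries$stage)
  if (!ref_stage %in% levels(stage)) {
    stop("reference stage '", ref_stage, "' not present in the data", call. = FALSE)
  }
  stage <- stats::relevel(stage, ref = ref_stage)

  groups <- if (mode == "crude") as.list(covariates) else list(covariates)
  n_dropped_total <- NA_integer_
  out <- list()
  fits <- list()
  for (cov in groups) {
    dat <- summaries[, cov, drop = FALSE]
    dat$.stage <- stage
    cc <- stats::complete.cases(dat)
    n_dropped <- sum(!cc)
    dat <- dat[cc, , drop = FALSE]
    for (cv in cov) {
      if (is.factor(dat[[cv]])) dat[[cv]] <- droplevels(dat[[cv]])
    }
    fml <- stats::as.formula(paste("~", paste(cov, collapse = " + ")))
    X <- stats::model.matrix(fml, data = dat)
    fit <- multinom_newton(X, dat$.stage, tol = tol, max_iter = max_iter)
    fit$n_dropped <- n_dropped
    lab <- paste(cov, collapse = "+")
    fits[[lab]] <- fit
    rows <- or_rows_from_fit(fit, covariate = lab, alpha = alpha)
    rows$mode <- mode
    rows$n <- fit$n
    rows$converged <- fit$converged
    if (!fit$converged) {
      warning(sprintf("multinomial fit for '%s' did not converge: %s", lab, fit$message),
              call. = FALSE)
    }
    out[[length(out) + 1]] <- rows
  }
  res <- purrr::list_rbind(out)
  attr(res, "fits") <- fits
  res
}

#' Expand a contingency table of counts to patient-level rows
#'
#' Convenience for fitting the multinomial model directly on printed
#' level-by-stage counts.
#'
#' @inheritParams crude_or_from_counts
#' @return Tibble with one row per patient: `level` (factor, reference level
#'   first) and `stage` (factor, reference stage first).
#' @export
expand_counts <- function(counts, ref_level = rownames(counts)[1],
                          ref_stage = colnames(counts)[1]) {
  lv <- c(ref_level, setdiff(rownames(counts), ref_level))
  st <- c(ref_stage, setdiff(colnames(counts), ref_stage))
  grid <- expand.grid(level = rownames(counts), stage = colnames(counts),
                      stringsAsFactors = FALSE)
  n <- mapply(function(l, s) counts[l, s], grid$level, grid$stage)
  tibble::tibble(
    level = factor(rep(grid$level, n), levels = lv),
    stage = factor(rep(grid$stage, n), levels = st)
  )
}

#' Characteristics table across cascade stages
#'
#' Tabulates each covariate against the four stages the way cohort
#' description tables do: categorical covariates get per-stage counts and
#' column percentages with a chi-square test of independence; numeric
#' covariates get per-stage means and SDs with a one-way ANOVA p-value.
#' Levels absent everywhere are dropped with a note. Percentages are rounded
#' half-up to 1 decimal for display.
#'
#' @param summaries patient-summary tibble with `stage`.
#' @param covariates character vector of column names.
#' @return Tidy tibble: `covariate`, `level` (`NA` for numeric), `stage`
#'   (including `"overall"`), `count`/`percent` or `mean`/`sd`, `p_value`
#'   (repeated within covariate).
#' @export
characteristics_table <- function(summaries, covariates) {
  stage <- factor(summaries$stage, levels = names(cascade_stages()))
  strata <- c(levels(stage), "overall")
  rows <- list()
  for (cov in covariates) {
    x <- summaries[[cov]]
    if (is.numeric(x)) {
      p <- tryCatch(summary(stats::aov(x ~ stage))[[1]][["Pr(>F)"]][1],
                    error = function(e) NA_real_)
      for (s in strata) {
        xi <- if (s == "overall") x else x[stage == s]
        rows[[length(rows) + 1]] <- tibble::tibble(
          covariate = cov, level = NA_character_, stage = s,
          count = NA_integer_, percent = NA_real_,
          mean = mean(xi, na.rm = TRUE), sd = stats::sd(xi, na.rm = TRUE),
          p_value = p)
      }
    } else {
      f <- droplevels(factor(x))
      tab <- table(f, stage)
      p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                    error = function(e) NA_real_)
      for (s in strata) {
        cnt <- unname(if (s == "overall") rowSums(tab) else tab[, s])
        rows[[length(rows) + 1]] <- tibble::tibble(
          covariate = cov, level = rownames(tab), stage = s,
          count = as.integer(cnt),
          percent = round_half_up(100 * cnt / sum(cnt), 1),
          mean = NA_real_, sd = NA_real_, p_value = p)
      }
    }
  }
  purrr::list_rbind(rows)
}
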