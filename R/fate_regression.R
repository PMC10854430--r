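# Regression models of NSC decisions: logistic regression of division
# propensity on apical area and deltaA status (with optional fish fixed
# effects and treatment interactions), type II Wald tests, probability
# rescaling between observation windows, and a multinomial model of
# division fate.

#' Build the per-track regression table
#'
#' One row per track: whether it divided, its apical area (area at the last
#' pre-division time point for dividers; average over the study period for
#' nondividers), its deltaA status (status before division for dividers;
#' most prevalent scored status for nondividers, ties resolved by the last
#' scored point), and the division fate (deltaA mode of the daughter pair
#' at `horizon`; `"none"` for nondividers, `NA` when unclassifiable).
#' Tracks without any area observation are excluded and counted in
#' attribute `"n_excluded"`.
#'
#' @param forest a `lineage_forest`.
#' @param min_quiet_intervals passed to [detect_divisions()].
#' @param horizon daughter-pair horizon for the fate label (default 0, the
#'   division time point).
#' @param delta_threshold score threshold for positivity.
#' @return data.frame with columns `track_id`, `fish_id`, `treatment`,
#'   `divided`, `area`, `delta_pos`, `fate`.
#' @export
build_regression_table <- function(forest, min_quiet_intervals = 2L,
                                   horizon = 0L, delta_threshold = 1L) {
  stopifnot(inherits(forest, "lineage_forest"))
  pts <- forest$points
  events <- detect_divisions(forest, min_quiet_intervals, delta_threshold)
  modes <- if (nrow(events) > 0L)
    classify_division_mode(events, forest, horizon, delta_threshold)
  else NULL
  ids <- unique(pts$track_id)
  out <- vector("list", length(ids))
  excluded <- 0L
  for (i in seq_along(ids)) {
    id <- ids[i]
    rows <- pts[pts$track_id == id, , drop = FALSE]
    n <- nrow(rows)
    divided <- rows$event[n] == "division"
    if (divided) {
      area <- rows$area_um2[n]
      dp <- delta_status(rows$delta_score[n], delta_threshold)
      fate <- modes$mode[modes$mother_track == id]
      if (length(fate) == 0L || fate == "unclassifiable") fate <- NA_character_
    } else {
      a <- rows$area_um2[!is.na(rows$area_um2)]
      area <- if (length(a)) mean(a) else NA_real_
      st <- delta_status(rows$delta_score, delta_threshold)
      st <- st[!is.na(st)]
      dp <- if (length(st) == 0L) NA
      else if (mean(st) > 0.5) TRUE
      else if (mean(st) < 0.5) FALSE
      else st[length(st)]
      fate <- "none"
    }
    if (is.na(area)) {
      excluded <- excluded + 1L
      next
    }
    out[[i]] <- data.frame(
      track_id = id, fish_id = rows$fish_id[1L],
      treatment = rows$treatment[1L], divided = divided, area = area,
      delta_pos = dp, fate = fate, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  attr(res, "n_excluded") <- excluded
  res
}

#' Logistic regression of division propensity
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of the
#' division indicator on the configured design. The default design uses
#' apical area, deltaA status and their interaction; fish fixed effects
#' enter as dummy-coded intercept shifts and a treatment-by-status
#' interaction can be added for pooled control/Notch-blockade tables. Area
#' enters in um^2 untransformed. Complete separation is detected (diverging
#' linear predictors) and flagged rather than silently penalized.
#'
#' @param rows regression table from [build_regression_table()] (or any
#'   data.frame with the referenced columns).
#' @param formula model formula; default `divided ~ area * delta_pos`. Add
#'   `+ fish_id` for fish fixed effects, `+ treatment:delta_pos` etc.
#' @return An object of class `division_fit`: list with `coefficients`,
#'   `vcov`, `loglik`, `wald` (per-term type II tests), `separation`,
#'   `converged`, `iter`, `formula`, `data`, and the underlying `glm`.
#' @export
fit_division_logistic <- function(rows,
                                  formula = divided ~ area * delta_pos) {
  y <- stats::model.frame(formula, rows)[[1L]]
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: only one class present (complete separation)",
         call. = FALSE)
  fit <- stats::glm(formula, family = stats::binomial(), data = rows,
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 50))
  eta <- stats::predict(fit, type = "link")
  separation <- max(abs(eta)) > 15
  if (separation)
    warning("possible complete separation: diverging linear predictor",
            call. = FALSE)
  obj <- structure(list(
    coefficients = stats::coef(fit),
    vcov = stats::vcov(fit),
    loglik = as.numeric(stats::logLik(fit)),
    separation = separation,
    converged = fit$converged,
    iter = fit$iter,
    formula = formula,
    data = rows,
    glm = fit), class = "division_fit")
  term_labels <- attr(stats::terms(formula), "term.labels")
  obj$wald <- do.call(rbind, lapply(term_labels, function(tm) {
    w <- wald_type2(obj, tm)
    data.frame(term = tm, chisq = w$chisq, df = w$df, p = w$p,
               stringsAsFactors = FALSE)
  }))
  obj
}

#' @export
print.division_fit <- function(x, ...) {
  cat("<division_fit> logistic regression:",
      deparse(x$formula), "\n")
  print(round(x$coefficients, 4))
  cat("type II Wald tests:\n")
  print(x$wald, row.names = FALSE)
  if (x$separation) cat("warning: possible complete separation\n")
  invisible(x)
}

#' Predicted division probability curves
#'
#' Evaluates the fitted model over an area grid for a given deltaA status
#' (and optional fish / treatment), giving the probability-versus-area
#' curves used to visualize how division propensity increases with apical
#' area for each status.
#'
#' @param fit a `division_fit`.
#' @param area numeric vector of areas (um^2).
#' @param delta_pos logical scalar status.
#' @param fish_id,treatment optional scalars for models with those terms.
#' @return data.frame `area`, `delta_pos`, `prob`.
#' @export
predict_division_prob <- function(fit, area, delta_pos,
                                  fish_id = NULL, treatment = NULL) {
  stopifnot(inherits(fit, "division_fit"))
  nd <- data.frame(area = area, delta_pos = delta_pos)
  if (!is.null(fish_id)) nd$fish_id <- fish_id
  if (!is.null(treatment)) nd$treatment <- treatment
  p <- stats::predict(fit$glm, newdata = nd, type = "response")
  data.frame(area = area, delta_pos = delta_pos, prob = as.numeric(p))
}

# does term `a` contain term `b` (strictly)? e.g. area:delta contains area
term_contains <- function(a, b) {
  va <- strsplit(a, ":", fixed = TRUE)[[1L]]
  vb <- strsplit(b, ":", fixed = TRUE)[[1L]]
  length(va) > length(vb) && all(vb %in% va)
}

#' Type II Wald test of a model term
#'
#' Wald chi-square test of a term's coefficient block respecting
#' marginality: a main effect is tested in the model with every
#' higher-order term containing it removed (refit), while the
#' highest-order interactions are tested in the full model. The p-value
#' comes from the chi-square distribution with the block's degrees of
#' freedom.
#'
#' @param fit a `division_fit`.
#' @param term a term label appearing in the fit's formula (e.g. `"area"`,
#'   `"area:delta_pos"`, `"fish_id"`).
#' @return list with `chisq`, `df`, `p`.
#' @export
wald_type2 <- function(fit, term) {
  stopifnot(inherits(fit, "division_fit"))
  labels <- attr(stats::terms(fit$formula), "term.labels")
  if (!(term %in% labels))
    stop("term not in design: ", term, call. = FALSE)
  relatives <- labels[vapply(labels, term_contains, logical(1), b = term)]
  if (length(relatives) > 0L) {
    reduced <- stats::update(fit$formula,
                             paste("~ . -", paste(relatives, collapse = " - ")))
    g <- stats::glm(reduced, family = stats::binomial(), data = fit$data,
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 50))
  } else {
    g <- fit$glm
  }
  asgn <- attr(stats::model.matrix(g), "assign")
  lbl <- attr(stats::terms(g), "term.labels")
  idx <- which(asgn == match(term, lbl))
  if (length(idx) == 0L)
    stop("no estimable coefficients for term ", term, call. = FALSE)
  b <- stats::coef(g)[idx]
  V <- stats::vcov(g)[idx, idx, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular covariance block for term ", term, call. = FALSE))
  chisq <- as.numeric(t(b) %*% Vi %*% b)
  df <- length(idx)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Rescale a window probability to another window
#'
#' Under a memoryless division process the probability of not dividing over
#' `k` days satisfies `1 - p_k = (1 - p_1)^k`, so a probability estimated
#' over one observation window rescales to another as
#' `1 - (1 - p)^(window_to / window_from)` — e.g. a 35-day estimate `p35`
#' maps to 4 days as `p4 = 1 - exp((4/35) * log(1 - p35))`. Used to compare
#' control fits (movie-long windows) with Notch-blockade fits (4-day
#' windows) on a common scale.
#'
#' @param p probability in [0, 1]; vectorized.
#' @param window_from,window_to window lengths in days (> 0).
#' @return Rescaled probability.
#' @export
rescale_probability <- function(p, window_from, window_to) {
  stopifnot(window_from > 0, window_to > 0)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p must lie in [0, 1]", call. = FALSE)
  if (any(p == 1, na.rm = TRUE))
    warning("p = 1 is degenerate under memorylessness; returning 1",
            call. = FALSE)
  ifelse(p == 1, 1, 1 - (1 - p)^(window_to / window_from))
}

#' Multinomial log-linear model of division fate
#'
#' Maximum-likelihood multinomial logit of the daughter-pair fate
#' (`neg_pos`, `pos_pos`, `neg_neg`) of dividing deltaA-negative mothers.
#' The default design has per-fish intercepts only — the model found
#' adequate for these data, in which case the fit is saturated per fish and
#' the fitted probabilities equal the per-fish empirical fate proportions.
#' Fitting is by BFGS on the multinomial log-likelihood with analytic
#' gradient (reference category = first observed fate level).
#'
#' @param rows data.frame with a `fate` column (and any covariates named in
#'   `formula`); typically the `divided & !delta_pos` subset of
#'   [build_regression_table()] output. Rows with missing fate are dropped.
#' @param formula right-hand-side design formula (default `~ fish_id`; use
#'   `~ 1` for a single intercept).
#' @return An object of class `fate_multinom`: list with `categories`,
#'   `coefficients` (matrix, one column per non-reference category),
#'   `loglik`, `fitted` (per-row category probabilities), `counts`, and
#'   `degenerate` (`TRUE` when a single fate category is present, in which
#'   case no model is fitted).
#' @export
fit_fate_multinomial <- function(rows, formula = ~ fish_id) {
  rows <- rows[!is.na(rows$fate) & rows$fate != "none", , drop = FALSE]
  if (nrow(rows) == 0L) stop("no fate observations", call. = FALSE)
  categories <- sort(unique(rows$fate))
  counts <- table(rows$fate)
  if (length(categories) < 2L) {
    return(structure(list(categories = categories, coefficients = NULL,
                          loglik = 0, fitted = NULL, counts = counts,
                          degenerate = TRUE), class = "fate_multinom"))
  }
  X <- stats::model.matrix(formula, rows)
  n <- nrow(X); p <- ncol(X); K <- length(categories)
  Y <- outer(rows$fate, categories, "==") * 1  # n x K indicator
  nll <- function(theta) {
    B <- matrix(theta, p, K - 1L)
    eta <- cbind(0, X %*% B)
    m <- apply(eta, 1, max)
    logZ <- m + log(rowSums(exp(eta - m)))
    -sum(rowSums(Y * eta) - logZ)
  }
  grad <- function(theta) {
    B <- matrix(theta, p, K - 1L)
    eta <- cbind(0, X %*% B)
    m <- apply(eta, 1, max)
    P <- exp(eta - m) / rowSums(exp(eta - m))
    G <- t(X) %*% (P - Y)  # p x K
    as.numeric(G[, -1L, drop = FALSE])
  }
  opt <- stats::optim(rep(0, p * (K - 1L)), nll, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  B <- matrix(opt$par, p, K - 1L,
              dimnames = list(colnames(X), categories[-1L]))
  eta <- cbind(0, X %*% B)
  m <- apply(eta, 1, max)
  P <- exp(eta - m) / rowSums(exp(eta - m))
  colnames(P) <- categories
  structure(list(categories = categories, coefficients = B,
                 loglik = -opt$value, fitted = P, counts = counts,
                 degenerate = FALSE, formula = formula, data = rows),
            class = "fate_multinom")
}

#' @export
print.fate_multinom <- function(x, ...) {
  if (x$degenerate) {
    cat("<fate_multinom> degenerate: single category",
        x$categories, "(n =", sum(x$counts), ")\n")
  } else {
    cat("<fate_multinom> categories:",
        paste(x$categories, collapse = ", "), "\n")
    cat("counts:\n"); print(x$counts)
  }
  invisible(x)
}

#' Fitted fate probabilities per fish
#'
#' For a fish-intercept fate model, the fitted category probabilities of
#' each fish (which equal the fish's empirical fate proportions when the
#' design is saturated).
#'
#' @param fit a `fate_multinom`.
#' @return data.frame `fish_id` + one probability column per category.
#' @export
fate_probs_by_fish <- function(fit) {
  stopifnot(inherits(fit, "fate_multinom"), !fit$degenerate)
  fish <- fit$data$fish_id
  out <- do.call(rbind, lapply(unique(fish), function(f) {
    i <- which(fish == f)[1L]
    cbind(data.frame(fish_id = f, stringsAsFactors = FALSE),
          as.data.frame(t(fit$fitted[i, ])))
  }))
  rownames(out) <- NULL
  out
}
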