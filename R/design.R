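#' Generate a three-level fractional factorial design with blocking
#'
#' Builds the `M^(k-p)`-run design used for robustness studies: a full
#' three-level factorial in the `k - p` base factors, generator columns
#' (modular sums of base-factor codings) for the remaining factors,
#' replicated across `blocks` blocks, with run order randomized within
#' block. Levels are coded -1, 0, 1. With the defaults
#' (`M = 3, k = 4, p = 2, blocks = 3`) this yields 27 runs, 9 per block,
#' each factor level appearing 9 times.
#'
#' @param M modality count per factor; only 3 is supported.
#' @param k number of factors (`>= p + 1`).
#' @param p number of factors generated from the base factorial.
#' @param blocks number of blocks (replicates of the treatment set).
#' @param seed optional integer randomizing the run order within blocks;
#'   `NULL` keeps the systematic order.
#' @param factor_names names for the `k` factor columns.
#' @return A tibble of class `design_matrix` with columns `run`, `block`
#'   and one column per factor; attributes `M`, `k`, `p`, `blocks`,
#'   `generators` (text description) record the construction.
#' @export
generate_design <- function(M = 3L, k = 4L, p = 2L, blocks = 3L, seed = NULL,
                            factor_names = c("cobb", "position", "mri",
                                             "user")) {
  if (M != 3L) stop("only three-level designs (M = 3) are supported")
  if (k < p + 1L) stop("`k` must be at least p + 1")
  if (blocks < 1L) stop("`blocks` must be >= 1")
  b <- k - p
  if (length(factor_names) != k)
    factor_names <- paste0("f", seq_len(k))
  base <- as.matrix(expand.grid(rep(list(0:2), b)))[, seq_len(b),
                                                    drop = FALSE]
  # generator coefficient sets over the base factors: all non-proportional
  # nonzero Z3 combinations that are not a single base factor
  cand <- as.matrix(expand.grid(rep(list(0:2), b)))
  cand <- cand[rowSums(cand) > 0, , drop = FALSE]
  cand <- cand[apply(cand != 0, 1, sum) > 1, , drop = FALSE]
  # drop scalar multiples (c and 2c give aliased columns)
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) if (keep[i] && i < nrow(cand))
    for (j in (i + 1):nrow(cand))
      if (all((2 * cand[i, ]) %% 3 == cand[j, ])) keep[j] <- FALSE
  cand <- cand[keep, , drop = FALSE]
  if (p > nrow(cand))
    stop("cannot construct ", p, " generators from ", b, " base factors")
  gens <- cand[seq_len(p), , drop = FALSE]
  full <- base
  for (g in seq_len(p))
    full <- cbind(full, (base %*% gens[g, ]) %% 3)
  colnames(full) <- factor_names
  runs_per_block <- nrow(full)
  rows <- list()
  for (bl in seq_len(blocks)) {
    ord <- seq_len(runs_per_block)
    if (!is.null(seed))
      ord <- with_seed(seed + bl, sample.int(runs_per_block))
    df <- as.data.frame(full[ord, , drop = FALSE] - 1L)
    df[] <- lapply(df, as.integer)
    df <- cbind(block = as.integer(bl), df)
    rows[[bl]] <- df
  }
  out <- do.call(rbind, rows)
  out <- cbind(run = seq_len(nrow(out)), out)
  out <- tibble::as_tibble(out)
  gen_txt <- vapply(seq_len(p), function(g)
    paste0(factor_names[b + g], " = (",
           paste(sprintf("%d*%s", gens[g, ], factor_names[seq_len(b)]),
                 collapse = " + "), ") mod 3"), "")
  structure(out, class = c("design_matrix", class(out)),
            M = M, k = k, p = p, blocks = blocks,
            factor_names = factor_names, generators = gen_txt)
}

# orthogonal linear/quadratic codings on the balanced levels {-1, 0, 1}:
# linear is the level itself, quadratic is 3*level^2 - 2 (values 1, -2, 1),
# both sum to zero and are mutually orthogonal
coding_linear <- function(level) as.numeric(level)
coding_quadratic <- function(level) 3 * as.numeric(level)^2 - 2

#' Estimate factor effects on a design response (ANOVA)
#'
#' Fits a linear model with the block as a categorical term and orthogonal
#' linear and quadratic contrasts for every factor; two-factor
#' (linear-by-linear) interaction terms are added only where they are
#' estimable (not aliased with columns already in the model — in the
#' default `3^(4-2)` design every two-factor interaction is aliased with
#' main effects and is reported as dropped). Standardized effects are
#' estimate / standard error (t statistics) with p-values on the residual
#' degrees of freedom.
#'
#' @param design a [generate_design()] tibble or any data frame with a
#'   `block` column and factor columns coded -1/0/1.
#' @param response numeric response, one value per run, or the name of a
#'   column of `design` holding it.
#' @param interactions attempt linear-by-linear two-factor interactions.
#' @return A tibble of class `effect_table` with `term`, `type`,
#'   `estimate`, `std_error`, `statistic`, `p_value`; attributes
#'   `df_residual`, `sigma` and `aliased` (dropped interaction terms).
#'   Quadratic terms carry the conventional `*` suffix.
#' @export
estimate_effects <- function(design, response = "response",
                             interactions = TRUE) {
  df <- as.data.frame(design)
  if (is.character(response) && length(response) == 1L) {
    if (!response %in% names(df))
      stop("response column `", response, "` not found")
    y <- df[[response]]
  } else {
    y <- as.numeric(response)
  }
  if (length(y) != nrow(df) || anyNA(y))
    stop("a response value is required for every run")
  fn <- attr(design, "factor_names")
  if (is.null(fn))
    fn <- setdiff(names(df), c("run", "block", "response"))
  X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  types <- "intercept"
  if ("block" %in% names(df) && length(unique(df$block)) > 1L) {
    bl <- factor(df$block)
    Bm <- stats::model.matrix(~bl)[, -1, drop = FALSE]
    colnames(Bm) <- paste0("block_", levels(bl)[-1])
    X <- cbind(X, Bm)
    types <- c(types, rep("block", ncol(Bm)))
  }
  for (f in fn) {
    X <- cbind(X, coding_linear(df[[f]]), coding_quadratic(df[[f]]))
    colnames(X)[ncol(X) - 1:0] <- c(f, paste0(f, "*"))
    types <- c(types, "linear", "quadratic")
  }
  aliased <- character(0)
  if (interactions && length(fn) >= 2L) {
    for (pair in utils::combn(fn, 2L, simplify = FALSE)) {
      col <- coding_linear(df[[pair[1]]]) * coding_linear(df[[pair[2]]])
      nm <- paste(pair, collapse = ":")
      if (qr(cbind(X, col))$rank > qr(X)$rank) {
        X <- cbind(X, col)
        colnames(X)[ncol(X)] <- nm
        types <- c(types, "interaction")
      } else {
        aliased <- c(aliased, nm)
      }
    }
  }
  n <- nrow(X)
  df_res <- n - ncol(X)
  if (df_res <= 0L)
    stop("saturated model: ", ncol(X), " parameters for ", n,
         " runs leaves ", df_res, " residual degrees of freedom")
  fit <- stats::lm.fit(X, y)
  est <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df_res
  XtXi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXi))
  stat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf))
  pval <- if (sigma2 > 0) 2 * pt(-abs(stat), df_res) else rep(NA_real_, length(stat))
  keep <- types != "intercept"
  out <- tibble::tibble(term = colnames(X)[keep], type = types[keep],
                        estimate = unname(est[keep]),
                        std_error = unname(se[keep]),
                        statistic = unname(stat[keep]),
                        p_value = unname(pval[keep]))
  structure(out, class = c("effect_table", class(out)),
            df_residual = df_res, sigma = sqrt(sigma2), aliased = aliased,
            intercept = unname(est[1]))
}

#' Pareto ranking of estimated effects
#'
#' Terms sorted by descending absolute standardized effect, flagged
#' significant at level `alpha` — the tabular form of the Pareto chart of
#' effects.
#'
#' @param effects an [estimate_effects()] table.
#' @param alpha significance level.
#' @return The effect table sorted by `abs(statistic)` descending with an
#'   added logical `significant` column and a `rank` column.
#' @export
pareto_ranking <- function(effects, alpha = 0.05) {
  stopifnot(inherits(effects, "effect_table"))
  ord <- order(-abs(effects$statistic))
  out <- effects[ord, ]
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out$rank <- seq_len(nrow(out))
  attr(out, "alpha") <- alpha
  out
}

#' @export
tidy.effect_table <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.effect_table <- function(x, ...) {
  tibble::tibble(df_residual = attr(x, "df_residual"),
                 sigma = attr(x, "sigma"),
                 n_terms = nrow(x),
                 n_aliased = length(attr(x, "aliased")))
}

#' Pareto chart of standardized effects
#'
#' @param object an [estimate_effects()] table.
#' @param alpha significance level for the reference line.
#' @param ... unused.
#' @return A ggplot object (requires the ggplot2 package).
#' @exportS3Method ggplot2::autoplot
autoplot.effect_table <- function(object, alpha = 0.05, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for autoplot()")
  pr <- pareto_ranking(object, alpha)
  pr$term <- factor(pr$term, levels = rev(pr$term))
  tcrit <- stats::qt(1 - alpha / 2, attr(object, "df_residual"))
  ggplot2::ggplot(pr, ggplot2::aes(x = abs(.data$statistic), y = .data$term,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = tcrit, linetype = "dashed") +
    ggplot2::labs(x = "|standardized effect| (t)", y = NULL,
                  title = "Pareto chart of effects",
                  subtitle = sprintf("dashed line: |t| at alpha = %.2f",
                                     alpha)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.effect_table
#' @param effects an [estimate_effects()] table.
#' @export
plot_pareto <- function(effects, alpha = 0.05) {
  autoplot.effect_table(effects, alpha = alpha)
}
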