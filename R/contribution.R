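#' Permutation importance of the environmental predictors
#'
#' Model-agnostic contribution measure: each predictor column of the
#' held-out set is shuffled `n_repeats` times (seeded) and the mean
#' increase in test MSE over the unshuffled baseline is recorded.
#' Negative mean increases (sampling noise around an irrelevant
#' predictor) are clipped to zero before normalizing the raw importances
#' to percent.
#'
#' @param model A fitted `ann_model`.
#' @param test_set Data.frame holding the model's feature columns and the
#'   target (>= 10 rows).
#' @param n_repeats Shuffles per predictor (default 100).
#' @param seed Integer seed for the shuffles.
#' @param target Target column name (default `"cpue"`).
#' @return A data.frame of class `contribution_report` with columns
#'   `predictor`, `raw_importance` (MSE increase), `percent`; attributes
#'   `method`, `n_repeats`, `seed`, `baseline_mse`.
#' @export
permutation_importance <- function(model, test_set, n_repeats = 100,
                                   seed = 1, target = "cpue") {
  stopifnot(inherits(model, "ann_model"))
  if (nrow(test_set) < 10)
    stop("need at least 10 held-out rows", call. = FALSE)
  feats <- model$feature_names
  miss <- setdiff(c(feats, target), names(test_set))
  if (length(miss))
    stop("test set missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  X <- as.matrix(test_set[, feats, drop = FALSE])
  y <- test_set[[target]]
  base_mse <- mean((y - ann_forward(model, X))^2)

  raw <- numeric(length(feats)); names(raw) <- feats
  with_local_seed(derive_seed(seed, "perm"), {
    for (p in feats) {
      if (length(unique(X[, p])) == 1) {
        warning("predictor '", p, "' is constant; importance set to 0")
        next
      }
      inc <- numeric(n_repeats)
      for (r in seq_len(n_repeats)) {
        Xp <- X
        Xp[, p] <- X[sample.int(nrow(X)), p]
        inc[r] <- mean((y - ann_forward(model, Xp))^2) - base_mse
      }
      raw[p] <- mean(inc)
    }
  })
  clipped <- pmax(raw, 0)
  if (sum(clipped) == 0)
    stop("all permutation importances are zero; model is insensitive to ",
         "every predictor", call. = FALSE)
  structure(data.frame(predictor = feats,
                       raw_importance = unname(raw),
                       percent = unname(clipped / sum(clipped) * 100)),
            method = "permutation", n_repeats = n_repeats, seed = seed,
            baseline_mse = base_mse,
            class = c("contribution_report", "data.frame"))
}

#' Connection-weight (Garson) contributions
#'
#' Partitions the network's connection weights among inputs: for hidden
#' neuron h and input i, the share `|W1[h,i]| / sum_i' |W1[h,i']|` is
#' weighted by `|w2[h]|`, summed over hidden neurons, and normalized to
#' percent.  A structural alternative to [permutation_importance()];
#' both are reported, neither is claimed to reproduce any published
#' contribution figure exactly.
#'
#' @param model A fitted `ann_model`.
#' @return A `contribution_report` data.frame (method
#'   `"connection-weight"`).
#' @export
connection_weight_contribution <- function(model) {
  stopifnot(inherits(model, "ann_model"))
  W1 <- abs(model$W1); w2 <- abs(model$w2)
  if (all(W1 == 0) || all(w2 == 0))
    stop("all-zero weights: contributions undefined", call. = FALSE)
  row_tot <- rowSums(W1)
  row_tot[row_tot == 0] <- 1
  Q <- (W1 / row_tot) * w2          # hidden x input shares
  raw <- colSums(Q)
  structure(data.frame(predictor = model$feature_names,
                       raw_importance = unname(raw),
                       percent = unname(raw / sum(raw) * 100)),
            method = "connection-weight", n_repeats = NA_integer_,
            seed = NA_integer_,
            class = c("contribution_report", "data.frame"))
}

#' Satellite vs in-situ validation statistics
#'
#' Pearson correlation, MSE and RMSE between paired satellite-derived and
#' in-situ measurements of the same quantity.
#'
#' @param in_situ,satellite Paired numeric series, equal length >= 3.
#' @return A list of class `validation_report`: `pearson_r` (`NA` when
#'   either series has zero variance), `mse`, `rmse`, `n`.
#' @examples
#' satellite_validation(1:5, 1:5 + 0.5)$rmse  # 0.5
#' @export
satellite_validation <- function(in_situ, satellite) {
  if (length(in_situ) != length(satellite))
    stop("paired series must have equal length", call. = FALSE)
  if (length(in_situ) < 3)
    stop("need at least 3 pairs", call. = FALSE)
  r <- if (stats::sd(in_situ) == 0 || stats::sd(satellite) == 0) {
    warning("zero variance in a series; correlation undefined")
    NA_real_
  } else stats::cor(in_situ, satellite)
  mse <- mean((in_situ - satellite)^2)
  structure(list(pearson_r = r, mse = mse, rmse = sqrt(mse),
                 n = length(in_situ)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Satellite validation (n = %d): r = %s, RMSE = %.4f\n",
              x$n, ifelse(is.na(x$pearson_r), "NA",
                          sprintf("%.3f", x$pearson_r)), x$rmse))
  invisible(x)
}

#' Bar chart of predictor contributions
#'
#' Base-graphics bar chart of percent contributions (the standard
#' contribution figure).
#'
#' @param report A `contribution_report`.
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_contribution <- function(report, ...) {
  stopifnot(inherits(report, "contribution_report"))
  graphics::barplot(report$percent, names.arg = toupper(report$predictor),
                    ylab = "Contribution (%)",
                    main = sprintf("Predictor contribution (%s)",
                                   attr(report, "method")), ...)
}
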