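feature_names <- c("hist_mean", "hist_std", "hist_skewness", "hist_entropy",
                   "theta_max_deg", "s_max", "s_var", "s_max_minus_mean")

#' Train the disk/background k-NN classifier
#'
#' Stores z-standardized training features (per-feature mean and standard
#' deviation from the training set), labels and the neighbour count.
#' Distance ties at prediction time are broken by training-row order, and
#' `k` must be odd so a two-class majority vote cannot tie.
#'
#' @param features a data frame / tibble with the eight feature columns and
#'   a `label` column (e.g. from [region_feature_table()]), or a list of
#'   labelled [region2d()].
#' @param k odd neighbour count, `1 <= k <=` sample count.
#' @return Object of class `knn_model`.
#' @export
train_knn <- function(features, k = 5L) {
  if (is.list(features) && !is.data.frame(features) &&
      all(vapply(features, inherits, TRUE, "region2d")))
    features <- region_feature_table(features)
  if (!is.data.frame(features) || !all(feature_names %in% names(features)) ||
      !"label" %in% names(features))
    stop("`features` must contain the eight feature columns and `label`")
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("`k` must be odd and >= 1")
  X <- as.matrix(features[, feature_names])
  y <- as.character(features$label)
  if (k > nrow(X)) stop("`k` cannot exceed the number of training samples")
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  centre <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale == 0] <- 1                     # constant feature: leave as-is
  Z <- sweep(sweep(X, 2, centre), 2, scale, "/")
  structure(list(training_features = Z, training_labels = y, k = k,
                 centre = centre, scale = scale),
            class = "knn_model")
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("<knn_model> k = %d, %d training rows (%s)\n", x$k,
              nrow(x$training_features),
              paste(names(table(x$training_labels)),
                    table(x$training_labels), sep = ":", collapse = ", ")))
  invisible(x)
}

#' @export
glance.knn_model <- function(x, ...) {
  tibble::tibble(n_train = nrow(x$training_features), k = x$k,
                 n_features = ncol(x$training_features),
                 classes = paste(sort(unique(x$training_labels)),
                                 collapse = "/"))
}

# predict labels for a raw (unstandardized) feature matrix
predict_knn <- function(model, X) {
  stopifnot(inherits(model, "knn_model"))
  X <- matrix(as.numeric(X), ncol = length(model$centre))
  Z <- sweep(sweep(X, 2, model$centre), 2, model$scale, "/")
  T_ <- model$training_features
  out <- character(nrow(Z))
  for (i in seq_len(nrow(Z))) {
    d <- sqrt(colSums((t(T_) - Z[i, ])^2))
    nb <- order(d)[seq_len(model$k)]         # stable: ties by row order
    votes <- table(model$training_labels[nb])
    out[i] <- names(votes)[which.max(votes)]
  }
  out
}

#' Label candidate regions with the k-NN classifier
#'
#' Each region is labelled by majority vote among its `k` nearest training
#' samples under Euclidean distance in standardized feature space.
#' Deterministic: `k` is odd and distance ties resolve by training-row
#' order. Applied to sagittal candidate regions only in the full pipeline
#' (coronal regions are matched later by anatomical correspondence).
#'
#' @param model a [train_knn()] model.
#' @param regions list of [region2d()]; features are computed where missing.
#' @param params list as in [classification_params()].
#' @return The same regions with `label` set to `"disk"` or `"background"`.
#' @export
classify_regions <- function(model, regions,
                             params = classification_params()) {
  stopifnot(inherits(model, "knn_model"))
  if (length(regions) == 0L) return(regions)
  regions <- lapply(regions, function(r)
    if (is.null(r$features)) region_features(r, params) else r)
  X <- do.call(rbind, lapply(regions, function(r) r$features[feature_names]))
  lab <- predict_knn(model, X)
  for (i in seq_along(regions)) regions[[i]]$label <- lab[i]
  regions
}

#' Persist / restore a k-NN model as JSON
#'
#' @param model a [train_knn()] model.
#' @param path file path.
#' @return `write_knn_model` returns `path` invisibly; `read_knn_model`
#'   the restored model.
#' @export
write_knn_model <- function(model, path) {
  stopifnot(inherits(model, "knn_model"))
  obj <- list(k = model$k, centre = as.list(model$centre),
              scale = as.list(model$scale),
              labels = model$training_labels,
              features = as.data.frame(model$training_features))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_knn_model
#' @export
read_knn_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(training_features = as.matrix(obj$features),
                 training_labels = as.character(obj$labels),
                 k = as.integer(obj$k),
                 centre = unlist(obj$centre), scale = unlist(obj$scale)),
            class = "knn_model")
}
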