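#' Mean absolute percentage error
#'
#' `MAPE(y) = 100/M * sum_i |(y_true,i - y_pred,i) / y_true,i|`, the mean
#' absolute relative deviation of predictions from ground truth, reported
#' as a percentage.
#'
#' @param predicted,truth Numeric vectors of equal length; truths must be
#'   non-zero.
#' @return MAPE in percent (non-negative scalar).
#' @examples
#' mape(c(1, 2, 4), c(1, 2.5, 4))  # 6.667
#' @export
mape <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("'predicted' and 'truth' must have the same length")
  if (length(truth) < 1) stop("need at least one value")
  if (any(!is.finite(predicted)) || any(!is.finite(truth)))
    stop("inputs must be finite")
  if (any(truth == 0)) stop("'truth' contains zero values")
  100 * mean(abs((truth - predicted) / truth))
}

#' Mean node distance between a profile and a reference contour
#'
#' Average over the nodes of `profile` of the Euclidean distance to the
#' nearest point of the closed polyline through the nodes of `reference`
#' (point-to-segment, not point-to-node), after aligning the two
#' centroids. Used to score how faithfully an extracted boundary
#' reproduces the generating profile.
#'
#' @param profile,reference `capsule_profile` objects or node matrices in
#'   the same units.
#' @return Mean distance (units of the inputs).
#' @export
profile_node_error <- function(profile, reference) {
  P <- unclass(as.matrix(profile)); Q <- unclass(as.matrix(reference))
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  A <- Q; B <- Q[c(2:nrow(Q), 1), , drop = FALSE]
  E <- B - A
  len2 <- pmax(rowSums(E^2), .Machine$double.eps)
  d <- vapply(seq_len(nrow(P)), function(i) {
    t <- pmin(pmax(((P[i, 1] - A[, 1]) * E[, 1] +
                      (P[i, 2] - A[, 2]) * E[, 2]) / len2, 0), 1)
    min(sqrt((A[, 1] + t * E[, 1] - P[i, 1])^2 +
               (A[, 2] + t * E[, 2] - P[i, 2])^2))
  }, 0)
  mean(d)
}

#' Parameter-recovery study over node counts, image resolutions and seeds
#'
#' The package's evaluation workbench: for every combination of membrane
#' node count, image resolution and seed it generates an independent
#' training and test dataset, trains the MLP on exact synthetic feature
#' vectors, evaluates the held-out MAPE of both capillary numbers and the
#' per-class confusion, and (optionally) scores the Hausdorff inverse
#' method on the same test set. When a finite `resolution` is given, each
#' test profile is first rasterised at that many pixels per undeformed
#' capsule diameter and re-extracted through the full image-processing
#' chain, so the study measures the end-to-end image pipeline; the mean
#' extraction error of the recovered nodes (in pixels) is recorded
#' alongside.
#'
#' @param node_counts Integer vector of membrane node counts.
#' @param resolutions Numeric vector of pixels per undeformed capsule
#'   diameter; `NA` entries test on exact (non-rasterised) vectors.
#' @param seeds Integer vector; every cell is run once per seed and the
#'   raw per-seed values are kept.
#' @param n_train,n_test Training and test set sizes.
#' @param ca_ks_range,ca_gs_range,beta,alpha Generation parameters, passed
#'   to [generate_dataset()].
#' @param control Base [mlp_control()]; its seed is replaced by the cell
#'   seed.
#' @param include_inverse Also run [inverse_predict()] against the
#'   training library on every test profile.
#' @param window_px Smoothing window of the extraction chain.
#' @return A `recovery_study`: list with `table` (one row per cell and
#'   seed: `mape_ca_ks`, `mape_ca_gs`, `nh_recall`, `extraction_error_px`,
#'   and `inv_mape_*` when requested), `confusion` (list of contingency
#'   tables), and `manifest`.
#' @examples
#' \donttest{
#' st <- run_recovery_study(node_counts = 20, seeds = 1, n_train = 120,
#'                          n_test = 30,
#'                          control = mlp_control(batch_size = 32,
#'                                                max_epochs = 60))
#' summary(st)
#' }
#' @export
run_recovery_study <- function(node_counts = 60, resolutions = NA,
                               seeds = 1:3, n_train = 400, n_test = 100,
                               ca_ks_range = c(0.02, 0.055),
                               ca_gs_range = c(0.03, 0.21),
                               beta = 0.77, alpha = 0.03,
                               control = mlp_control(),
                               include_inverse = FALSE, window_px = 9) {
  grid <- expand.grid(node_count = node_counts, resolution = resolutions,
                      seed = seeds)
  rows <- vector("list", nrow(grid))
  confusion <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    nd <- grid$node_count[g]; res <- grid$resolution[g]; sd_ <- grid$seed[g]
    train_ds <- generate_dataset(n_train, ca_ks_range, ca_gs_range,
                                 beta = beta, alpha = alpha, n_nodes = nd,
                                 seed = sd_)
    test_ds <- generate_dataset(n_test, ca_ks_range, ca_gs_range,
                                beta = beta, alpha = alpha, n_nodes = nd,
                                seed = sd_ + 7919L)
    truth <- as.data.frame(test_ds)
    ex_err <- NA_real_
    if (is.finite(res)) {
      ppr <- res / (2 * (1 + alpha) * beta)
      errs <- numeric(n_test)
      vecs <- lapply(seq_len(n_test), function(i) {
        prof <- dataset_profile(test_ds, i)
        img <- rasterize_profile(prof, px_per_diameter = res)
        got <- extract_profile(img, n_nodes = nd, window_px = window_px)
        errs[i] <<- profile_node_error(got, prof) * ppr
        to_feature_vector(got)
      })
      X_test <- do.call(rbind, vecs)
      ex_err <- mean(errs)
    } else {
      X_test <- do.call(rbind, lapply(test_ds$samples, `[[`, "vector"))
    }
    ctl <- control; ctl$seed <- sd_
    fit <- capsule_mlp(train_ds, ctl)
    pred <- predict(fit, X_test)
    conf <- table(truth = factor(truth$kind, law_kinds),
                  predicted = factor(pred$kind, law_kinds))
    row <- data.frame(node_count = nd, resolution = res, seed = sd_,
                      mape_ca_ks = mape(pred$ca_ks, truth$ca_ks),
                      mape_ca_gs = mape(pred$ca_gs, truth$ca_gs),
                      nh_recall = conf["NH", "NH"] / max(sum(conf["NH", ]), 1),
                      extraction_error_px = ex_err)
    if (include_inverse) {
      lib <- profile_library(train_ds)
      inv <- lapply(seq_len(nrow(X_test)), function(i)
        inverse_predict(matrix(X_test[i, ], ncol = 2, byrow = TRUE), lib))
      row$inv_mape_ca_ks <- mape(vapply(inv, `[[`, 0, "ca_ks"),
                                 truth$ca_ks)
      row$inv_mape_ca_gs <- mape(vapply(inv, `[[`, 0, "ca_gs"),
                                 truth$ca_gs)
      inv_kind <- vapply(inv, `[[`, "", "kind")
      row$inv_nh_recall <- sum(inv_kind == "NH" & truth$kind == "NH") /
        max(sum(truth$kind == "NH"), 1)
    }
    rows[[g]] <- row
    confusion[[g]] <- conf
  }
  structure(list(table = do.call(rbind, rows), confusion = confusion,
                 manifest = list(node_counts = node_counts,
                                 resolutions = resolutions, seeds = seeds,
                                 n_train = n_train, n_test = n_test,
                                 ca_ks_range = ca_ks_range,
                                 ca_gs_range = ca_gs_range,
                                 beta = beta, alpha = alpha,
                                 control = unclass(control),
                                 include_inverse = include_inverse,
                                 window_px = window_px)),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat("capsule parameter-recovery study\n")
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' Seed-averaged study table
#'
#' @param object A `recovery_study`.
#' @param ... Unused.
#' @return Data frame with per-cell means and standard deviations over
#'   seeds.
#' @export
summary.recovery_study <- function(object, ...) {
  tb <- object$table
  key <- paste(tb$node_count,
               ifelse(is.na(tb$resolution), "exact", tb$resolution))
  agg <- lapply(split(tb, key), function(d) {
    out <- data.frame(node_count = d$node_count[1],
                      resolution = d$resolution[1],
                      n_seeds = nrow(d))
    for (v in intersect(c("mape_ca_ks", "mape_ca_gs", "nh_recall",
                          "extraction_error_px", "inv_mape_ca_ks",
                          "inv_mape_ca_gs"), names(d))) {
      out[[paste0(v, "_mean")]] <- mean(d[[v]])
      out[[paste0(v, "_sd")]] <- if (nrow(d) > 1) stats::sd(d[[v]]) else NA_real_
    }
    out
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Write a study report to CSV and JSON
#'
#' Writes the raw per-seed table as CSV and the manifest plus seed-averaged
#' summary as JSON next to it.
#'
#' @param study A `recovery_study`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "recovery_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$table, file.path(dir, "study_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(manifest = study$manifest,
         summary = summary(study)),
    file.path(dir, "study_summary.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
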