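#' Mean Hausdorff distance between two point sets
#'
#' The directed mean Hausdorff distance from the observed set `R` to the
#' template set `T`,
#' \deqn{\bar h(R, T) = \frac{1}{m} \sum_{r \in R} \min_{t \in T} d(r, t),}
#' the average over the `m` points of `R` of the Euclidean distance to the
#' nearest point of `T`. It is asymmetric by construction:
#' `mean_hausdorff(R, T)` is zero whenever every point of `R` coincides
#' with some point of `T`, regardless of how much of `T` is left
#' uncovered. Both sets are translated to a common centre of mass before
#' evaluation (the convention under which profile comparisons are made),
#' unless `align = FALSE`.
#'
#' @param R,T Two-column matrices of point coordinates (`capsule_profile`
#'   objects are accepted).
#' @param symmetric If `TRUE`, return the larger of the two directed means
#'   (the symmetric variant); default `FALSE` (directed, observation to
#'   template).
#' @param align Translate both sets to a common centroid first (default
#'   `TRUE`).
#' @return Non-negative scalar distance (units of the coordinates).
#' @examples
#' mean_hausdorff(rbind(c(0, 0), c(1, 0)), rbind(c(0, 0), c(0, 1)),
#'                align = FALSE)  # 0.5
#' @export
mean_hausdorff <- function(R, T, symmetric = FALSE, align = TRUE) {
  R <- unclass(as.matrix(R)); T <- unclass(as.matrix(T))
  if (nrow(R) == 0 || nrow(T) == 0) stop("point sets must be non-empty")
  if (align) {
    R <- sweep(R, 2, colMeans(R))
    T <- sweep(T, 2, colMeans(T))
  }
  h <- directed_mhd(R, T)
  if (symmetric) h <- max(h, directed_mhd(T, R))
  h
}

# Mean over rows of A of the distance to the nearest row of B. Squared
# distances are formed from explicit differences (no expanded-product
# shortcut), so coincident points give exactly zero.
directed_mhd <- function(A, B) {
  best <- rep(Inf, nrow(A))
  for (j in seq_len(nrow(B)))
    best <- pmin(best, (A[, 1] - B[j, 1])^2 + (A[, 2] - B[j, 2])^2)
  mean(sqrt(best))
}

#' Labelled profile library for the inverse method
#'
#' Builds the template library the inverse method scans: one entry per
#' sample of a generated dataset, holding the profile nodes and the
#' mechanical labels.
#'
#' @param dataset A `capsule_dataset` from [generate_dataset()].
#' @return A `profile_library`: list with `profiles` (list of node
#'   matrices), `labels` (data frame of `kind`, `ca_ks`, `ca_gs`) and
#'   `manifest`.
#' @export
profile_library <- function(dataset) {
  stopifnot(inherits(dataset, "capsule_dataset"),
            length(dataset$samples) > 0)
  profiles <- lapply(dataset$samples, function(s)
    matrix(s$vector, ncol = 2, byrow = TRUE))
  structure(list(profiles = profiles,
                 labels = as.data.frame(dataset),
                 manifest = dataset$manifest),
            class = "profile_library")
}

#' @export
print.profile_library <- function(x, ...) {
  cat(sprintf("profile library: %d labelled entries, %d nodes each\n",
              length(x$profiles), nrow(x$profiles[[1]])))
  invisible(x)
}

#' Inverse prediction by minimum mean Hausdorff distance
#'
#' The baseline inverse method: linearly scans every entry of a labelled
#' profile library, computes the directed mean Hausdorff distance from the
#' observed profile to each template (both centred on their mass centres),
#' and returns the labels of the best-fitting (minimum-MHD) entry. Ties are
#' broken towards the lowest entry index.
#'
#' @param profile A `capsule_profile` (or node matrix) in the library's
#'   node convention.
#' @param library A [profile_library()].
#' @param symmetric Use the symmetric MHD variant (default `FALSE`).
#' @return List with `kind`, `ca_ks`, `ca_gs`, `mhd` (the best distance,
#'   tube-radius units) and `index` (the matched entry).
#' @examples
#' lib <- profile_library(generate_dataset(n = 30, seed = 1))
#' inverse_predict(steady_profile("NH", 0.03, 0.09), lib)
#' @export
inverse_predict <- function(profile, library, symmetric = FALSE) {
  stopifnot(inherits(library, "profile_library"))
  obs <- unclass(as.matrix(profile))
  d <- vapply(library$profiles, function(tpl)
    mean_hausdorff(obs, tpl, symmetric = symmetric), 0)
  i <- which.min(d)
  list(kind = library$labels$kind[i],
       ca_ks = library$labels$ca_ks[i],
       ca_gs = library$labels$ca_gs[i],
       mhd = d[i], index = i)
}
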