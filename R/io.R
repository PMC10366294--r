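#' Write and read a dataset as a directory of plain-text files
#'
#' The on-disk form of a `capsule_dataset`: one CSV of node coordinates
#' per sample (`sample_0001.csv`, ... with columns `node`, `x`, `y`), a
#' label table `labels.csv` (columns `sample`, `kind`, `ca_ks`, `ca_gs`),
#' and a JSON `manifest.json` holding the generation arguments. A dataset
#' is reproducible bit-for-bit from the manifest alone via
#' [generate_dataset()]; the files exist for interchange with external
#' tools.
#'
#' @param dataset A `capsule_dataset`.
#' @param dir Target directory (created if missing).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()` a
#'   `capsule_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "capsule_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(dataset), file.path(dir, "labels.csv"),
                   row.names = FALSE)
  for (i in seq_along(dataset$samples)) {
    nodes <- matrix(dataset$samples[[i]]$vector, ncol = 2, byrow = TRUE)
    utils::write.csv(
      data.frame(node = seq_len(nrow(nodes)), x = nodes[, 1],
                 y = nodes[, 2]),
      file.path(dir, sprintf("sample_%04d.csv", i)), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  labels <- utils::read.csv(file.path(dir, "labels.csv"),
                            stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(labels)), function(i) {
    nodes <- utils::read.csv(file.path(dir, sprintf("sample_%04d.csv", i)))
    list(vector = as.vector(t(as.matrix(nodes[, c("x", "y")]))),
         kind = labels$kind[i], ca_ks = labels$ca_ks[i],
         ca_gs = labels$ca_gs[i])
  })
  structure(list(samples = samples, manifest = as.list(manifest)),
            class = "capsule_dataset")
}
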