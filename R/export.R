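#' Write a rank table as TSV
#'
#' Layout: `node`, `p`, `k`, `p_star`, `k_star`, `k2`, `in_degree`,
#' `out_degree`, `ce_in`, `ce_out`.
#'
#' @param tab A [rank_table()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rank_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write reduced-Google-matrix components and a JSON sidecar
#'
#' Each component is a labeled dense TSV matrix (row = target,
#' column = source, matching the column-stochastic convention); the sidecar
#' `<prefix>.json` stores lambda_c, the component weights, the negative
#' weight of G_qr and the series term count.
#'
#' @param rgm A `reduced_google`.
#' @param prefix Output path prefix; files `<prefix>_<component>.tsv` and
#'   `<prefix>.json` are written.
#' @return Character vector of written paths, invisibly.
#' @export
write_reduced <- function(rgm, prefix) {
  stopifnot(inherits(rgm, "reduced_google"))
  comps <- c("g_rr", "g_pr", "g_qr", "g_qrd", "g_qrnd")
  paths <- character(0)
  for (cm in comps) {
    p <- paste0(prefix, "_", cm, ".tsv")
    utils::write.table(rgm[[cm]], p, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
    paths <- c(paths, p)
  }
  side <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(lambda_c = rgm$lambda_c, one_minus_lambda_c = rgm$one_minus_lambda_c,
         w_rr = rgm$weights[["w_rr"]], w_pr = rgm$weights[["w_pr"]],
         w_qr = rgm$weights[["w_qr"]],
         negative_weight = rgm$negative_weight, n_terms = rgm$n_terms,
         alpha = rgm$alpha, n = rgm$n, n_r = length(rgm$subset)),
    side, auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, side))
}

#' Write hidden interactions as SIF plus a score TSV
#'
#' The SIF file (`source hidden target`) loads alongside the input networks;
#' the companion TSV carries scores and class labels.
#'
#' @param hidden A [infer_hidden()] result.
#' @param sif_path,tsv_path Output paths.
#' @return Written paths, invisibly.
#' @export
write_hidden <- function(hidden, sif_path, tsv_path) {
  stopifnot(inherits(hidden, "hidden_interactions"))
  writeLines(paste(hidden$source, "hidden", hidden$target, sep = "\t"), sif_path)
  utils::write.table(as.data.frame(hidden), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(sif_path, tsv_path))
}

#' Write a spectrum as TSV
#'
#' Layout: `index`, `re`, `im`, `mod`, `ipr`.
#'
#' @param spec A `spectrum_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spec, path) {
  utils::write.table(tidy(spec), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
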