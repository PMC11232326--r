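RESULT_COLUMNS <- c("sender", "receiver", "metabolite_id", "metabolite_name",
                    "receptor", "E", "T", "M", "R", "MR_score", "p_value",
                    "q_value")

fmt_num <- function(x) trimws(formatC(x, digits = 6, format = "g"))

#' Write a communication results table
#'
#' Tab-delimited file with a \code{#}-prefixed header block recording the
#' tool version, the full configuration and md5 digests of the input files,
#' followed by a fixed column order. Numbers carry 6 significant digits; for
#' a fixed input and seed the file is byte-identical across runs, so results
#' are diffable.
#'
#' @param results An \code{mlr_results} table from \code{\link{run_analysis}}
#'   (or any data.frame with the same columns; \code{MR} is accepted for
#'   \code{MR_score}).
#' @param path Output file path.
#' @param inputs Optional named character vector of input file paths to
#'   digest into the header.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(results, path, inputs = character(0)) {
  df <- as.data.frame(results)
  if (!"MR_score" %in% names(df) && "MR" %in% names(df))
    df$MR_score <- df$MR
  missing <- setdiff(RESULT_COLUMNS, names(df))
  if (length(missing))
    stop(sprintf("write_results: missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  cfg <- attr(results, "config")
  header <- c(
    sprintf("# mlrcomm results v%s", as.character(utils::packageVersion("mlrcomm"))),
    if (!is.null(cfg)) sprintf("# config: %s",
      paste(sprintf("%s=%s", names(unclass(cfg)),
                    vapply(unclass(cfg), function(v) format(v, scientific = FALSE),
                           character(1))), collapse = " ")),
    if (length(inputs)) sprintf("# input %s: md5=%s",
      if (is.null(names(inputs))) basename(inputs) else names(inputs),
      unname(tools::md5sum(inputs))))
  num <- intersect(RESULT_COLUMNS, c("E", "T", "M", "R", "MR_score",
                                     "p_value", "q_value"))
  out <- df[, RESULT_COLUMNS, drop = FALSE]
  for (cl in num) out[[cl]] <- fmt_num(out[[cl]])
  con <- file(path, open = "wb")  # binary: fixed "\n" endings for byte-stability
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  writeLines(paste(RESULT_COLUMNS, collapse = "\t"), con, sep = "\n")
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Read back a results file written by \code{\link{write_results}}
#' @param path Results file path.
#' @return data.frame with the standard result columns, numerics parsed.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  missing <- setdiff(RESULT_COLUMNS, names(df))
  if (length(missing))
    stop(sprintf("read_results: missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Bubble plot of significant communication triples
#'
#' One dot per triple with p <= alpha: x = sender -> receiver pair, y =
#' metabolite -- receptor pair, dot size proportional to -log10(p) (capped at
#' 4, i.e. p = 1e-4, since permutation p-values are bounded below anyway) and
#' color encoding the MR score. When no triple passes the threshold an
#' annotated empty plot is written so pipelines always get an image.
#'
#' @param results Results table (from \code{\link{run_analysis}} or
#'   \code{\link{read_results}}).
#' @param alpha Significance threshold for inclusion.
#' @param path Output image path (extension selects the device: .png/.pdf).
#' @param width,height Device size in inches.
#' @return \code{path}, invisibly.
#' @export
bubble_plot <- function(results, alpha = 0.05, path = "bubble.png",
                        width = 8, height = 6) {
  df <- as.data.frame(results)
  if (!"MR_score" %in% names(df) && "MR" %in% names(df)) df$MR_score <- df$MR
  sig <- df[df$p_value <= alpha, , drop = FALSE]
  if (nrow(sig) == 0L) {
    gg <- ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0,
                        label = sprintf("no interaction with p <= %g", alpha)) +
      ggplot2::theme_void()
  } else {
    sig$pair <- paste(sig$sender, "→", sig$receiver)
    sig$axis_y <- paste(sig$metabolite_name, "—", sig$receptor)
    sig$neglogp <- pmin(-log10(sig$p_value), 4)
    gg <- ggplot2::ggplot(sig, ggplot2::aes(
            x = pair, y = axis_y, size = neglogp, color = MR_score)) +
      ggplot2::geom_point() +
      ggplot2::scale_size_continuous(name = "-log10(p)", range = c(2, 8),
                                     limits = c(0, 4)) +
      ggplot2::scale_color_viridis_c(name = "MR score") +
      ggplot2::labs(x = "sender → receiver", y = "metabolite — receptor") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
  ggplot2::ggsave(path, gg, width = width, height = height, dpi = 150)
  invisible(path)
}
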