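#' Analysis configuration
#'
#' Bundles and validates the tunable parameters of a communication run.
#'
#' @param min_frac_pct N, in percent: a gene is kept for a cell type only if
#'   it is expressed (value > 0) in at least N\% of that type's cells.
#'   Enzymes and transporters are filtered against the sender, receptor
#'   subunits against the receiver. Default 10.
#' @param n_perm Number of label permutations for the empirical p-value.
#'   Default 100.
#' @param alpha Reporting significance threshold (used by the bubble plot and
#'   CLI filtering; all rows are always retained in the results table).
#' @param seed RNG seed making the permutation pass reproducible.
#' @param negative_e_policy \code{"literal"} squares a negative net enzyme
#'   expression as the availability formula is written; \code{"clamp"} floors
#'   E at 0 first. See \code{\link{metabolite_availability}}.
#' @param normalization \code{"cpm"} (rescale each cell to sum 10,000; for
#'   raw counts) or \code{"none"} (for TPM-like input).
#' @param include_autocrine Include sender == receiver pairs? Default TRUE:
#'   metabolites act locally and self-signaling is biologically real.
#' @return Object of class \code{mlr_config}.
#' @export
analysis_config <- function(min_frac_pct = 10, n_perm = 100, alpha = 0.05,
                            seed = 0L,
                            negative_e_policy = c("literal", "clamp"),
                            normalization = c("cpm", "none"),
                            include_autocrine = TRUE) {
  negative_e_policy <- match.arg(negative_e_policy)
  normalization <- match.arg(normalization)
  if (!is.numeric(min_frac_pct) || min_frac_pct < 0 || min_frac_pct > 100)
    stop("config error: min_frac_pct must lie in [0, 100]", call. = FALSE)
  if (!is.numeric(n_perm) || n_perm < 1)
    stop("config error: n_perm must be >= 1", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("config error: alpha must lie in (0, 1]", call. = FALSE)
  structure(list(min_frac_pct = as.numeric(min_frac_pct),
                 n_perm = as.integer(n_perm), alpha = as.numeric(alpha),
                 seed = as.integer(seed),
                 negative_e_policy = negative_e_policy,
                 normalization = normalization,
                 include_autocrine = isTRUE(include_autocrine)),
            class = "mlr_config")
}

#' Expressed-fraction filter
#'
#' A gene passes for a cell type iff its expressed fraction times 100 is at
#' least N (the boundary passes: the filter removes genes expressed in
#' *fewer* than N\% of cells). Genes absent from the expression matrix are
#' never retained, including at N = 0.
#'
#' @param profile \code{\link{profile_cell_types}} output.
#' @param genes Candidate gene symbols.
#' @param cell_type One cell-type label present in the profile.
#' @param min_frac_pct Threshold N in [0, 100].
#' @return Character vector: the retained subset of \code{genes}, in input
#'   order.
#' @export
apply_fraction_filter <- function(profile, genes, cell_type, min_frac_pct) {
  stopifnot(inherits(profile, "mlr_profile"))
  if (!cell_type %in% profile$cell_types)
    stop(sprintf("unknown cell type: %s", cell_type), call. = FALSE)
  present <- genes[genes %in% rownames(profile$expr_frac)]
  present[profile$expr_frac[present, cell_type] * 100 >= min_frac_pct]
}

# Precompute, per deduplicated interaction, integer row indices into the gene
# universe for its producer / consumer / transporter / receptor-subunit sets.
# NA indices mark KB genes absent from the matrix; the filter drops them.
build_triple_index <- function(kb, gene_universe) {
  stopifnot(inherits(kb, "mlr_kb"))
  if (length(intersect(kb_genes(kb), gene_universe)) == 0L)
    stop(paste("no overlap between knowledgebase genes and matrix genes --",
               "likely a species or symbol-case mismatch"), call. = FALSE)
  ia <- kb$interactions
  key <- paste(ia$metabolite_id, ia$receptor_canonical, sep = "\r")
  ia <- ia[!duplicated(key), , drop = FALSE]
  met_names <- stats::setNames(kb$metabolites$name, kb$metabolites$metabolite_id)
  ez <- kb$enzymes
  tr <- kb$transporters
  lapply(seq_len(nrow(ia)), function(i) {
    mid <- ia$metabolite_id[i]
    subs <- receptor_subunits(ia$receptor_canonical[i])
    prod <- ez$gene[ez$metabolite_id == mid & ez$role %in% c("producer", "both")]
    cons <- ez$gene[ez$metabolite_id == mid & ez$role %in% c("consumer", "both")]
    trans <- tr$gene[tr$metabolite_id == mid]
    list(metabolite_id = mid,
         metabolite_name = unname(met_names[mid]),
         receptor = ia$receptor_canonical[i],
         sub_ix = match(subs, gene_universe),
         prod_ix = match(unique(prod), gene_universe),
         cons_ix = match(unique(cons), gene_universe),
         trans_ix = match(unique(trans), gene_universe))
  })
}

gm_idx <- function(values) {
  # geometric mean specialized for pre-validated non-negative means
  if (length(values) == 0L) return(0)
  if (any(values == 0)) return(0)
  exp(mean(log(values)))
}

# Score every (sender, receiver, interaction) triple on one profile.
# Returns one row per triple in a fixed enumeration order with receptor_pass
# marking whether all subunits survived the receiver-side filter.
score_triples <- function(mean_expr, expr_frac, index, pairs, config) {
  pass <- expr_frac * 100 >= config$min_frac_pct  # genes x types
  n_tr <- nrow(pairs) * length(index)
  out <- data.frame(
    sender = character(n_tr), receiver = character(n_tr),
    metabolite_id = character(n_tr), metabolite_name = character(n_tr),
    receptor = character(n_tr),
    E = numeric(n_tr), T = numeric(n_tr), M = numeric(n_tr),
    R = numeric(n_tr), MR = numeric(n_tr), receptor_pass = logical(n_tr),
    stringsAsFactors = FALSE)
  row <- 0L
  clamp <- config$negative_e_policy == "clamp"
  for (p in seq_len(nrow(pairs))) {
    s <- pairs$sender[p]; r <- pairs$receiver[p]
    pass_s <- pass[, s]; pass_r <- pass[, r]
    mean_s <- mean_expr[, s]; mean_r <- mean_expr[, r]
    for (tri in index) {
      row <- row + 1L
      keep <- function(ix) ix[!is.na(ix)][pass_s[ix[!is.na(ix)]]]
      prod_ix <- keep(tri$prod_ix)
      cons_ix <- keep(tri$cons_ix)
      trans_ix <- keep(tri$trans_ix)
      E <- gm_idx(mean_s[prod_ix]) - gm_idx(mean_s[cons_ix])
      Tv <- gm_idx(mean_s[trans_ix])
      e2 <- if (clamp) max(E, 0) else E
      M <- sqrt(e2 * e2 + Tv * Tv)
      rec_ok <- !anyNA(tri$sub_ix) && all(pass_r[tri$sub_ix])
      R <- if (rec_ok) gm_idx(mean_r[tri$sub_ix]) else 0
      out$sender[row] <- s; out$receiver[row] <- r
      out$metabolite_id[row] <- tri$metabolite_id
      out$metabolite_name[row] <- tri$metabolite_name
      out$receptor[row] <- tri$receptor
      out$E[row] <- E; out$T[row] <- Tv; out$M[row] <- M; out$R[row] <- R
      out$MR[row] <- if (rec_ok) sqrt(M * M + R * R) else 0
      out$receptor_pass[row] <- rec_ok
    }
  }
  out
}

sender_receiver_pairs <- function(cell_types, include_autocrine = TRUE) {
  pairs <- expand.grid(sender = cell_types, receiver = cell_types,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!include_autocrine)
    pairs <- pairs[pairs$sender != pairs$receiver, , drop = FALSE]
  pairs[order(pairs$sender, pairs$receiver, method = "radix"), , drop = FALSE]
}

#' Score all communication triples (no significance yet)
#'
#' Enumerates every ordered (sender, receiver) cell-type pair (autocrine
#' included when configured) crossed with every knowledgebase interaction,
#' applies the N\% expressed-fraction filter (enzyme/transporter sets in the
#' sender, receptor subunits in the receiver) and computes E, T, M, R and the
#' MR score. Triples whose receptor complex has any subunit failing the
#' receiver filter are dropped from the table; triples that score MR = 0 are
#' retained but flagged untestable (\code{testable = FALSE}).
#'
#' @param profile \code{\link{profile_cell_types}} output.
#' @param kb An \code{mlr_kb}.
#' @param config An \code{\link{analysis_config}}.
#' @return data.frame with columns sender, receiver, metabolite_id,
#'   metabolite_name, receptor, E, T, M, R, MR, testable.
#' @export
score_pass <- function(profile, kb, config = analysis_config()) {
  stopifnot(inherits(profile, "mlr_profile"), inherits(config, "mlr_config"))
  index <- build_triple_index(kb, rownames(profile$mean_expr))
  pairs <- sender_receiver_pairs(profile$cell_types, config$include_autocrine)
  tab <- score_triples(profile$mean_expr, profile$expr_frac, index, pairs, config)
  tab <- tab[tab$receptor_pass, , drop = FALSE]
  tab$receptor_pass <- NULL
  tab$testable <- tab$MR > 0
  rownames(tab) <- NULL
  tab
}

#' Permutation p-values for scored triples
#'
#' For each of \code{n_perm} permutations, cell-type labels are shuffled
#' uniformly over all cells (type sizes preserved) and the entire pipeline --
#' per-type profiling, N\% filtering, scoring -- is recomputed. The one-sided
#' empirical p-value for a triple is (1 + b) / (n_perm + 1), where b counts
#' permutations whose recomputed MR is >= the observed MR. A triple skipped
#' in a permutation (receptor filtered out) contributes permuted MR = 0.
#' Untestable triples (observed MR = 0) receive p = 1.
#'
#' The RNG seed is taken from \code{config$seed}; the function restores the
#' caller's RNG state on exit.
#'
#' @param expr Normalized genes x cells matrix.
#' @param meta Named character vector, cell -> cell type (covering all
#'   matrix cells).
#' @param kb An \code{mlr_kb}.
#' @param config An \code{\link{analysis_config}}.
#' @param observed Output of \code{\link{score_pass}} on the unpermuted
#'   labels of the same matrix and config.
#' @return Numeric p-values aligned with \code{observed} rows.
#' @export
permutation_pvalues <- function(expr, meta, kb, config, observed) {
  stopifnot(inherits(config, "mlr_config"))
  if (config$n_perm < 1L) stop("config error: n_perm must be >= 1", call. = FALSE)
  cells <- colnames(expr)
  labels <- unname(meta[cells])
  if (anyNA(labels))
    stop("data error: matrix cell(s) missing from META", call. = FALSE)
  index <- build_triple_index(kb, rownames(expr))
  pairs <- sender_receiver_pairs(sort(unique(labels)), config$include_autocrine)

  # align observed rows to the fixed enumeration grid of score_triples
  grid_key <- as.vector(t(outer(
    paste(pairs$sender, pairs$receiver, sep = "\r"),
    vapply(index, function(tr) paste(tr$metabolite_id, tr$receptor, sep = "\r"),
           character(1)),
    paste, sep = "\r")))
  obs_key <- paste(observed$sender, observed$receiver, observed$metabolite_id,
                   observed$receptor, sep = "\r")
  pos <- match(obs_key, grid_key)
  if (anyNA(pos))
    stop("observed table does not match the (cell type, interaction) grid",
         call. = FALSE)

  exceed <- integer(nrow(observed))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(config$seed)
  for (b in seq_len(config$n_perm)) {
    perm_meta <- stats::setNames(sample(labels), cells)
    prof <- profile_cell_types(expr, perm_meta)
    tab <- score_triples(prof$mean_expr, prof$expr_frac, index, pairs, config)
    perm_mr <- ifelse(tab$receptor_pass, tab$MR, 0)[pos]
    exceed <- exceed + (perm_mr >= observed$MR)
  }
  p <- (1 + exceed) / (config$n_perm + 1)
  p[!observed$testable] <- 1
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment over a vector of p-values. The
#' pipeline applies it jointly over all *testable* triples and assigns q = 1
#' to untestable ones.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return q-values of the same length.
#' @export
adjust_bh <- function(p_values) {
  if (length(p_values) && (any(p_values <= 0) || any(p_values > 1)))
    stop("adjust_bh: p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Run the full communication analysis
#'
#' read -> normalize -> profile -> score -> permute -> adjust, deterministic
#' for a fixed seed. The output is sorted by (p ascending, MR descending,
#' sender, receiver, metabolite_id, receptor) -- a total order, so two runs
#' with identical inputs and seed produce byte-identical files.
#'
#' @param expr Genes x cells matrix, or a path understood by
#'   \code{\link{read_expression}}.
#' @param meta Named character vector (cell -> type), or a path for
#'   \code{\link{read_metadata}}.
#' @param kb An \code{mlr_kb} object, or a directory for
#'   \code{\link{read_kb_dir}} (then \code{species} is required).
#' @param config An \code{\link{analysis_config}}.
#' @param format Expression format when \code{expr} is a path.
#' @param species KB species when \code{kb} is a directory.
#' @return Object of class \code{mlr_results} (a data.frame): sender,
#'   receiver, metabolite_id, metabolite_name, receptor, E, T, M, R, MR,
#'   p_value, q_value, testable; the config is attached as
#'   \code{attr(, "config")}.
#' @examples
#' kb <- make_toy_kb(3, seed = 1)
#' d <- generate_planted_dataset(kb,
#'   planted_truth("T1", "T2", kb$interactions$metabolite_id[1], effect_size = 8),
#'   seed = 1)
#' res <- run_analysis(d$expr, d$meta, kb, analysis_config(n_perm = 49, seed = 1))
#' head(res, 3)
#' @export
run_analysis <- function(expr, meta, kb, config = analysis_config(),
                         format = c("dense_tsv", "mtx_dir"), species = NULL) {
  stopifnot(inherits(config, "mlr_config"))
  if (is.character(expr)) expr <- read_expression(expr, match.arg(format))
  if (is.character(meta) && is.null(names(meta)) && length(meta) == 1L)
    meta <- read_metadata(meta)
  if (is.character(kb)) {
    if (is.null(species)) stop("species is required when kb is a path", call. = FALSE)
    kb <- read_kb_dir(kb, species)
  }
  extra <- setdiff(names(meta), colnames(expr))
  if (length(extra)) {
    warning(sprintf("run_analysis: ignoring %d META cell(s) absent from the matrix",
                    length(extra)), call. = FALSE)
    meta <- meta[setdiff(names(meta), extra)]
  }
  if (length(unique(meta)) < 2L)
    stop("data error: need at least 2 distinct cell types", call. = FALSE)

  expr <- normalize_expression(expr, config$normalization)
  meta <- meta[colnames(expr)]  # normalization may drop all-zero cells
  prof <- profile_cell_types(expr, meta)
  tab <- score_pass(prof, kb, config)
  tab$p_value <- permutation_pvalues(expr, meta, kb, config, tab)
  tab$q_value <- rep(1, nrow(tab))
  tab$q_value[tab$testable] <- adjust_bh(tab$p_value[tab$testable])

  ord <- order(tab$p_value, -tab$MR, tab$sender, tab$receiver,
               tab$metabolite_id, tab$receptor, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "config") <- config
  class(tab) <- c("mlr_results", class(tab))
  tab
}
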