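METABOLITE_CLASSES <- c(
  "Lipids", "Organic acids and derivatives", "Benzenoids",
  "Nucleosides, nucleotides, and analogues", "Organic nitrogen compounds",
  "Organic oxygen compounds", "Organoheterocyclic compounds",
  "Homogeneous metal compounds", "Homogeneous non-metal compounds")

# run code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a toy knowledgebase
#'
#' Fabricates a valid single-species KB whose shape mirrors real annotation:
#' each metabolite gets 1-3 producer enzymes, 1-3 consumer enzymes, 0-2
#' dual-role ("both") enzymes, 0-2 transporters and exactly one receptor,
#' which is a 2-subunit complex with probability \code{complex_fraction}.
#' All gene symbols are synthetic and disjoint across roles and metabolites.
#' Deterministic for a fixed seed.
#'
#' @param n_metabolites Number of metabolites (>= 1).
#' @param complex_fraction Probability a receptor has two subunits.
#' @param seed RNG seed.
#' @param species KB species label.
#' @return An \code{mlr_kb} passing \code{\link{validate_kb}} with no errors.
#' @export
make_toy_kb <- function(n_metabolites = 10, complex_fraction = 0.3, seed = 0L,
                        species = "human") {
  stopifnot(n_metabolites >= 1)
  with_seed(seed, {
    mets <- sprintf("MET%03d", seq_len(n_metabolites))
    metabolites <- data.frame(
      metabolite_id = mets,
      name = sprintf("metabolite-%03d", seq_len(n_metabolites)),
      hmdb_id = sprintf("HMDB%07d", seq_len(n_metabolites)),
      pubchem_cid = as.character(seq_len(n_metabolites) + 1000L),
      class_label = sample(METABOLITE_CLASSES, n_metabolites, replace = TRUE),
      stringsAsFactors = FALSE)
    enz <- list(); trs <- list(); ints <- list()
    for (i in seq_len(n_metabolites)) {
      n_p <- sample(1:3, 1); n_c <- sample(1:3, 1)
      n_b <- sample(0:2, 1); n_t <- sample(0:2, 1)
      q <- if (stats::runif(1) < complex_fraction) 2L else 1L
      enz[[i]] <- data.frame(
        metabolite_id = mets[i],
        gene = c(sprintf("PR%03dG%d", i, seq_len(n_p)),
                 sprintf("CS%03dG%d", i, seq_len(n_c)),
                 if (n_b > 0) sprintf("BT%03dG%d", i, seq_len(n_b))),
        role = c(rep("producer", n_p), rep("consumer", n_c),
                 rep("both", n_b)),
        stringsAsFactors = FALSE)
      trs[[i]] <- if (n_t > 0) data.frame(
        metabolite_id = mets[i],
        gene = sprintf("TR%03dG%d", i, seq_len(n_t)),
        stringsAsFactors = FALSE)
      ints[[i]] <- data.frame(
        metabolite_id = mets[i],
        receptor = paste(sprintf("RC%03d%s", i, LETTERS[seq_len(q)]),
                         collapse = ";"),
        species = species, source = "synthetic",
        stringsAsFactors = FALSE)
    }
    kb_create(species, metabolites, do.call(rbind, ints),
              do.call(rbind, enz),
              do.call(rbind, trs[!vapply(trs, is.null, logical(1))]))
  })
}

nb_counts <- function(n, base_rate, dispersion) {
  if (base_rate == 0) return(numeric(n))
  stats::rnbinom(n, mu = base_rate, size = 1 / dispersion)
}

#' Generate a label-exchangeable null dataset
#'
#' Every gene's counts are drawn i.i.d. across *all* cells from one
#' negative-binomial distribution (mean \code{base_rate}, variance
#' \code{base_rate + dispersion * base_rate^2}), so cell-type labels carry no
#' information and are exchangeable by construction -- the correct null for
#' calibrating the permutation test. Labels are assigned in fixed contiguous
#' blocks \code{T1..Tk}. Genes are the KB's genes plus
#' \code{n_background} decoy genes, so library sizes and the N\% filter see
#' realistic context.
#'
#' @param kb An \code{mlr_kb} supplying the gene universe.
#' @param n_types Number of cell types (>= 2). Default 3.
#' @param cells_per_type Cells per type. Default 50.
#' @param base_rate Mean count per gene per cell. Default 5.
#' @param dispersion NB dispersion (0 = Poisson limit). Default 0.5.
#' @param n_background Extra non-KB genes. Default 20.
#' @param seed RNG seed.
#' @return List with \code{expr} (genes x cells count matrix) and \code{meta}
#'   (named character vector cell -> type).
#' @export
generate_null_dataset <- function(kb, n_types = 3, cells_per_type = 50,
                                  base_rate = 5, dispersion = 0.5,
                                  n_background = 20, seed = 0L) {
  stopifnot(n_types >= 2, cells_per_type >= 1)
  genes <- c(kb_genes(kb), if (n_background > 0)
    sprintf("BG%03d", seq_len(n_background)))
  n_cells <- n_types * cells_per_type
  with_seed(seed, {
    expr <- matrix(nb_counts(length(genes) * n_cells, base_rate, dispersion),
                   nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes, sprintf("cell%04d", seq_len(n_cells))))
    types <- sprintf("T%d", seq_len(n_types))
    meta <- stats::setNames(rep(types, each = cells_per_type), colnames(expr))
    list(expr = expr, meta = meta)
  })
}

#' Describe a planted communication signal
#'
#' @param sender,receiver Cell-type labels (as produced by the generators:
#'   \code{"T1"}, \code{"T2"}, ...).
#' @param metabolite_id Planted metabolite (must exist in the KB).
#' @param receptor Canonical receptor string; default \code{NULL} picks the
#'   metabolite's first annotated receptor.
#' @param effect_size Multiplicative elevation factor, > 1.
#' @return Object of class \code{mlr_planted_truth}.
#' @export
planted_truth <- function(sender, receiver, metabolite_id, receptor = NULL,
                          effect_size = 8) {
  if (!is.numeric(effect_size) || effect_size <= 1)
    stop("planted_truth: effect_size must be > 1", call. = FALSE)
  structure(list(sender = sender, receiver = receiver,
                 metabolite_id = metabolite_id, receptor = receptor,
                 effect_size = effect_size),
            class = "mlr_planted_truth")
}

#' Generate a dataset with one planted communication signal
#'
#' Starts from the null backbone of \code{\link{generate_null_dataset}},
#' then multiplies the planted metabolite's producer-enzyme and transporter
#' genes by \code{effect_size} in the sender's cells, suppresses its consumer
#' genes there (factor \code{1/effect_size}, keeping net enzyme expression
#' positive) and multiplies the receptor subunit genes by \code{effect_size}
#' in the receiver's cells. Dual-role ("both") enzymes appear in both the
#' producer and consumer products and are left untouched. At large effect
#' sizes the planted (sender, receiver, interaction) triple attains the
#' maximum MR score.
#'
#' @inheritParams generate_null_dataset
#' @param truth A \code{\link{planted_truth}} referencing KB entries.
#' @return List with \code{expr}, \code{meta} and the resolved \code{truth}
#'   (its \code{receptor} filled in).
#' @export
generate_planted_dataset <- function(kb, truth, n_types = 3,
                                     cells_per_type = 50, base_rate = 5,
                                     dispersion = 0.5, n_background = 20,
                                     seed = 0L) {
  stopifnot(inherits(truth, "mlr_planted_truth"))
  if (!truth$metabolite_id %in% kb$interactions$metabolite_id)
    stop(sprintf("planted metabolite '%s' has no interaction in the KB",
                 truth$metabolite_id), call. = FALSE)
  cand <- kb$interactions$receptor_canonical[
    kb$interactions$metabolite_id == truth$metabolite_id]
  if (is.null(truth$receptor)) {
    truth$receptor <- cand[1L]
  } else {
    truth$receptor <- canonical_receptor(truth$receptor)
    if (!truth$receptor %in% cand)
      stop(sprintf("planted receptor '%s' is not annotated for '%s'",
                   truth$receptor, truth$metabolite_id), call. = FALSE)
  }
  null <- generate_null_dataset(kb, n_types, cells_per_type, base_rate,
                                dispersion, n_background, seed)
  expr <- null$expr; meta <- null$meta
  for (ct in c(truth$sender, truth$receiver))
    if (!ct %in% meta)
      stop(sprintf("planted cell type '%s' not among generated types (%s)",
                   ct, paste(unique(meta), collapse = ", ")), call. = FALSE)

  ez <- kb$enzymes[kb$enzymes$metabolite_id == truth$metabolite_id, , drop = FALSE]
  boost <- unique(c(ez$gene[ez$role == "producer"],
                    kb$transporters$gene[
                      kb$transporters$metabolite_id == truth$metabolite_id]))
  suppress <- unique(ez$gene[ez$role == "consumer"])
  subunits <- receptor_subunits(truth$receptor)

  s_cells <- names(meta)[meta == truth$sender]
  r_cells <- names(meta)[meta == truth$receiver]
  expr[boost, s_cells] <- expr[boost, s_cells, drop = FALSE] * truth$effect_size
  expr[suppress, s_cells] <- expr[suppress, s_cells, drop = FALSE] / truth$effect_size
  expr[subunits, r_cells] <- expr[subunits, r_cells, drop = FALSE] * truth$effect_size
  list(expr = expr, meta = meta, truth = truth)
}
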