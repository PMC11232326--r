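#' @title Metabolite-ligand-receptor knowledgebase
#' @description
#' The knowledgebase (KB) holds, for one species, the metabolite records,
#' the metabolite <-> receptor(-complex) interactions, the role-tagged enzyme
#' annotations (producer / consumer / both) and the transporter annotations
#' that drive communication scoring. On disk it is four UTF-8 tab-delimited
#' tables with fixed headers:
#' \itemize{
#'   \item \code{interactions.tsv}: metabolite_id, receptor, species, source
#'   \item \code{enzymes.tsv}: metabolite_id, gene, role
#'   \item \code{transporters.tsv}: metabolite_id, gene
#'   \item \code{metabolites.tsv}: metabolite_id, name, hmdb_id, pubchem_cid,
#'     class_label
#' }
#' Receptor complexes are encoded as subunit symbols joined with \code{";"};
#' complex identity is order-insensitive (canonical form = sorted subunits).
#' @name mlr_kb
NULL

KB_ROLES <- c("producer", "consumer", "both")
KB_SPECIES <- c("human", "mouse")

#' Canonical receptor-complex identity
#'
#' Splits a \code{";"}-joined subunit string, sorts the subunits and rejoins
#' them, so that order-insensitive complex equality reduces to string
#' equality. Vectorized.
#'
#' @param receptor Character vector of \code{";"}-joined subunit symbols.
#' @return Character vector of canonical complex strings.
#' @export
canonical_receptor <- function(receptor) {
  vapply(strsplit(as.character(receptor), ";", fixed = TRUE), function(s) {
    s <- trimws(s)
    paste(sort(s), collapse = ";")
  }, character(1))
}

#' Subunits of a receptor complex
#' @param receptor A single \code{";"}-joined subunit string.
#' @return Character vector of subunit symbols (q >= 1).
#' @export
receptor_subunits <- function(receptor) {
  trimws(strsplit(as.character(receptor), ";", fixed = TRUE)[[1]])
}

read_tsv_checked <- function(path, required, file_label) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("format error in %s (%s): missing required column(s): %s",
                 file_label, path, paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Construct a knowledgebase from in-memory tables
#'
#' Low-level constructor used by the readers, the synthetic generator and
#' tests. With \code{strict = TRUE} (default) structural violations --
#' unresolved metabolite_id foreign keys, unknown enzyme roles, duplicate
#' receptor subunits -- throw; with \code{strict = FALSE} the object is built
#' as-is so \code{\link{validate_kb}} can report its problems.
#'
#' @param species \code{"human"} or \code{"mouse"}.
#' @param metabolites data.frame with column metabolite_id (name, hmdb_id,
#'   pubchem_cid, class_label filled with \code{""} when absent).
#' @param interactions data.frame with columns metabolite_id, receptor
#'   (\code{";"}-joined subunits), and optionally species, source.
#' @param enzymes data.frame with columns metabolite_id, gene, role.
#' @param transporters data.frame with columns metabolite_id, gene.
#' @param strict Throw on structural violations?
#' @return An object of class \code{mlr_kb}.
#' @export
kb_create <- function(species, metabolites, interactions, enzymes, transporters,
                      strict = TRUE) {
  species <- match.arg(species, KB_SPECIES)
  as_chr_df <- function(df, cols) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    for (cl in cols) if (is.null(df[[cl]])) df[[cl]] <- character(nrow(df))
    df[cols] <- lapply(df[cols], as.character)
    df[, cols, drop = FALSE]
  }
  metabolites  <- as_chr_df(metabolites,
                            c("metabolite_id", "name", "hmdb_id", "pubchem_cid", "class_label"))
  interactions <- as_chr_df(interactions, c("metabolite_id", "receptor", "species", "source"))
  enzymes      <- as_chr_df(enzymes, c("metabolite_id", "gene", "role"))
  transporters <- as_chr_df(transporters, c("metabolite_id", "gene"))
  interactions$species[interactions$species == ""] <- species
  interactions$receptor_canonical <- if (nrow(interactions)) {
    canonical_receptor(interactions$receptor)
  } else character(0)

  kb <- structure(list(species = species, metabolites = metabolites,
                       interactions = interactions, enzymes = enzymes,
                       transporters = transporters),
                  class = "mlr_kb")
  if (strict) {
    issues <- validate_kb(kb)
    errs <- issues[issues$severity == "error", , drop = FALSE]
    if (nrow(errs) > 0L)
      stop(sprintf("knowledgebase has %d error(s):\n%s", nrow(errs),
                   paste(sprintf("  [%s] %s", errs$entity, errs$message),
                         collapse = "\n")), call. = FALSE)
  }
  kb
}

#' Read a knowledgebase from its four TSV tables
#'
#' @param interactions_path,enzymes_path,transporters_path,metabolites_path
#'   Paths to the four tab-delimited tables (see \link{mlr_kb} for headers).
#' @param species \code{"human"} or \code{"mouse"}.
#' @param strict Throw on referential-integrity or vocabulary errors
#'   (default); \code{FALSE} defers to \code{\link{validate_kb}}.
#' @return An \code{mlr_kb} object.
#' @seealso \code{\link{read_kb_dir}} for the conventional directory layout.
#' @export
read_kb <- function(interactions_path, enzymes_path, transporters_path,
                    metabolites_path, species, strict = TRUE) {
  interactions <- read_tsv_checked(interactions_path,
                                   c("metabolite_id", "receptor"), "interactions table")
  enzymes <- read_tsv_checked(enzymes_path,
                              c("metabolite_id", "gene", "role"), "enzymes table")
  transporters <- read_tsv_checked(transporters_path,
                                   c("metabolite_id", "gene"), "transporters table")
  metabolites <- read_tsv_checked(metabolites_path,
                                  c("metabolite_id", "name"), "metabolites table")
  kb_create(species, metabolites, interactions, enzymes, transporters,
            strict = strict)
}

#' Read a knowledgebase directory
#'
#' Convenience wrapper over \code{\link{read_kb}} for a directory containing
#' \code{interactions.tsv}, \code{enzymes.tsv}, \code{transporters.tsv} and
#' \code{metabolites.tsv}.
#' @param dir Directory path.
#' @inheritParams read_kb
#' @return An \code{mlr_kb} object.
#' @export
read_kb_dir <- function(dir, species, strict = TRUE) {
  read_kb(file.path(dir, "interactions.tsv"), file.path(dir, "enzymes.tsv"),
          file.path(dir, "transporters.tsv"), file.path(dir, "metabolites.tsv"),
          species, strict = strict)
}

#' Write a knowledgebase to its four-table TSV layout
#'
#' Inverse of \code{\link{read_kb_dir}}; the round trip preserves canonical
#' complex identity and all annotation rows.
#' @param kb An \code{mlr_kb} object.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_kb <- function(kb, dir) {
  stopifnot(inherits(kb, "mlr_kb"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  ia <- kb$interactions
  ia$receptor_canonical <- NULL
  wt(ia, "interactions.tsv")
  wt(kb$enzymes, "enzymes.tsv")
  wt(kb$transporters, "transporters.tsv")
  wt(kb$metabolites, "metabolites.tsv")
  invisible(dir)
}

kb_issue <- function(severity, entity, message) {
  data.frame(severity = severity, entity = entity, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a knowledgebase
#'
#' Structural and referential checks; never throws. Broken foreign keys,
#' unknown enzyme roles, empty identifiers and duplicate complex subunits are
#' errors; duplicate interactions / annotation rows and orphan annotations
#' (metabolite never used by any interaction) are warnings, because real
#' enzyme and transporter annotation outstrips interaction coverage.
#'
#' @param kb An \code{mlr_kb} object.
#' @return data.frame with columns severity (\code{"error"}/\code{"warning"}),
#'   entity, message; zero rows when the KB is clean.
#' @export
validate_kb <- function(kb) {
  stopifnot(inherits(kb, "mlr_kb"))
  out <- list()
  met_ids <- kb$metabolites$metabolite_id

  if (any(met_ids == ""))
    out <- c(out, list(kb_issue("error", "metabolites", "empty metabolite_id")))
  dup_met <- unique(met_ids[duplicated(met_ids)])
  if (length(dup_met))
    out <- c(out, list(kb_issue("error", "metabolites",
      sprintf("duplicate metabolite_id: %s", paste(dup_met, collapse = ", ")))))

  fk_check <- function(df, entity) {
    bad <- unique(setdiff(df$metabolite_id, met_ids))
    if (length(bad))
      kb_issue("error", entity,
               sprintf("metabolite_id not in metabolites table: %s",
                       paste(bad, collapse = ", ")))
  }
  out <- c(out, list(fk_check(kb$interactions, "interactions")),
                list(fk_check(kb$enzymes, "enzymes")),
                list(fk_check(kb$transporters, "transporters")))

  if (nrow(kb$interactions)) {
    subs <- strsplit(kb$interactions$receptor, ";", fixed = TRUE)
    bad_sub <- vapply(subs, function(s) {
      s <- trimws(s)
      length(s) < 1L || any(s == "") || anyDuplicated(s) > 0L
    }, logical(1))
    if (any(bad_sub))
      out <- c(out, list(kb_issue("error", "interactions",
        sprintf("empty or duplicated receptor subunits in: %s",
                paste(unique(kb$interactions$receptor[bad_sub]), collapse = ", ")))))
    key <- paste(kb$interactions$metabolite_id, kb$interactions$receptor_canonical,
                 kb$interactions$species, sep = "\r")
    dup <- unique(key[duplicated(key)])
    if (length(dup))
      out <- c(out, list(kb_issue("warning", "interactions",
        sprintf("%d duplicated (metabolite, receptor, species) interaction(s)",
                length(dup)))))
    if (!all(kb$interactions$species == kb$species))
      out <- c(out, list(kb_issue("error", "interactions",
        sprintf("interaction species differs from KB species '%s'", kb$species))))
  }

  if (nrow(kb$enzymes)) {
    bad_role <- unique(setdiff(kb$enzymes$role, KB_ROLES))
    if (length(bad_role))
      out <- c(out, list(kb_issue("error", "enzymes",
        sprintf("unknown role value(s): %s (allowed: %s)",
                paste(bad_role, collapse = ", "), paste(KB_ROLES, collapse = ", ")))))
    key <- paste(kb$enzymes$metabolite_id, kb$enzymes$gene, sep = "\r")
    if (anyDuplicated(key))
      out <- c(out, list(kb_issue("warning", "enzymes",
        "duplicated (metabolite_id, gene) enzyme annotation(s)")))
  }
  if (nrow(kb$transporters)) {
    key <- paste(kb$transporters$metabolite_id, kb$transporters$gene, sep = "\r")
    if (anyDuplicated(key))
      out <- c(out, list(kb_issue("warning", "transporters",
        "duplicated (metabolite_id, gene) transporter annotation(s)")))
  }

  used <- unique(kb$interactions$metabolite_id)
  orphan <- function(df, entity) {
    orph <- unique(setdiff(intersect(df$metabolite_id, met_ids), used))
    if (length(orph))
      kb_issue("warning", entity,
               sprintf("annotation(s) for metabolite(s) with no interaction: %s",
                       paste(orph, collapse = ", ")))
  }
  out <- c(out, list(orphan(kb$enzymes, "enzymes")),
                list(orphan(kb$transporters, "transporters")))

  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(severity = character(0), entity = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Summarize a knowledgebase
#'
#' Entry counts, enzyme role breakdown and metabolite class distribution.
#' \code{n_metabolites} counts distinct metabolites referenced by at least
#' one interaction; \code{n_receptors} counts distinct canonical complexes.
#' Role percentages are 100 * count / enzyme entries, rounded to one decimal
#' (all 0.0 for an empty enzyme table).
#'
#' @param kb An \code{mlr_kb} object.
#' @return An object of class \code{mlr_kb_summary}: a list with
#'   n_interactions, n_metabolites, n_receptors, n_enzyme_entries,
#'   n_transporter_entries, role_counts, role_percentages, class_counts.
#' @export
summarize_kb <- function(kb) {
  stopifnot(inherits(kb, "mlr_kb"))
  n_enz <- nrow(kb$enzymes)
  role_counts <- vapply(KB_ROLES, function(r) sum(kb$enzymes$role == r), integer(1))
  role_pct <- if (n_enz > 0L) round(100 * role_counts / n_enz, 1) else
    stats::setNames(rep(0, length(KB_ROLES)), KB_ROLES)
  cls <- kb$metabolites$class_label
  cls <- cls[!is.na(cls) & cls != ""]
  class_counts <- if (length(cls)) {
    tb <- table(cls)
    stats::setNames(as.integer(tb), names(tb))
  } else stats::setNames(integer(0), character(0))
  structure(list(
    species = kb$species,
    n_interactions = nrow(kb$interactions),
    n_metabolites = length(unique(kb$interactions$metabolite_id)),
    n_receptors = length(unique(kb$interactions$receptor_canonical)),
    n_enzyme_entries = n_enz,
    n_transporter_entries = nrow(kb$transporters),
    role_counts = role_counts,
    role_percentages = role_pct,
    class_counts = class_counts
  ), class = "mlr_kb_summary")
}

#' @export
print.mlr_kb_summary <- function(x, ...) {
  cat(sprintf("ML-R knowledgebase summary (%s)\n", x$species))
  cat(sprintf("  interactions:       %d\n", x$n_interactions))
  cat(sprintf("  metabolites (used): %d\n", x$n_metabolites))
  cat(sprintf("  receptor complexes: %d\n", x$n_receptors))
  cat(sprintf("  enzyme entries:     %d\n", x$n_enzyme_entries))
  for (r in names(x$role_counts))
    cat(sprintf("    %-9s %5d (%.1f%%)\n", r, x$role_counts[[r]],
                x$role_percentages[[r]]))
  cat(sprintf("  transporter entries: %d\n", x$n_transporter_entries))
  if (length(x$class_counts)) {
    cat("  metabolite classes:\n")
    for (cl in names(x$class_counts))
      cat(sprintf("    %-40s %d\n", cl, x$class_counts[[cl]]))
  }
  invisible(x)
}

#' @export
print.mlr_kb <- function(x, ...) {
  cat(sprintf("mlr_kb (%s): %d interactions, %d metabolite records, %d enzyme entries, %d transporter entries\n",
              x$species, nrow(x$interactions), nrow(x$metabolites),
              nrow(x$enzymes), nrow(x$transporters)))
  invisible(x)
}

#' All gene symbols referenced by a knowledgebase
#' @param kb An \code{mlr_kb} object.
#' @return Character vector of distinct symbols (receptor subunits, enzymes,
#'   transporters).
#' @export
kb_genes <- function(kb) {
  stopifnot(inherits(kb, "mlr_kb"))
  unique(c(unlist(strsplit(kb$interactions$receptor, ";", fixed = TRUE)),
           kb$enzymes$gene, kb$transporters$gene))
}

#' Read a two-column orthology table
#'
#' @param path TSV with header columns source_gene, target_gene.
#' @return Named character vector mapping source symbol -> target symbol.
#' @export
read_orthology <- function(path) {
  df <- read_tsv_checked(path, c("source_gene", "target_gene"), "orthology table")
  as_orthology_map(df)
}

as_orthology_map <- function(omap) {
  if (is.data.frame(omap)) {
    if (!all(c("source_gene", "target_gene") %in% names(omap)))
      stop("orthology table needs columns source_gene, target_gene", call. = FALSE)
    omap <- stats::setNames(as.character(omap$target_gene),
                            as.character(omap$source_gene))
  }
  if (!is.character(omap) || is.null(names(omap)))
    stop("orthology map must be a named character vector or two-column data.frame",
         call. = FALSE)
  if (any(names(omap) == "") || any(omap == ""))
    stop("orthology map contains empty gene symbols", call. = FALSE)
  if (anyDuplicated(names(omap))) {
    # keep the first target per source so the map is a function
    omap <- omap[!duplicated(names(omap))]
  }
  omap
}

#' Map a knowledgebase to another species through an orthology table
#'
#' Replaces every gene symbol (receptor subunits, enzymes, transporters) via
#' the source -> target map. Entries touching any unmapped symbol are dropped:
#' a receptor complex is all-or-nothing, while enzyme and transporter
#' annotations are dropped independently of the interactions they accompany.
#' Metabolite records pass through unchanged. The numbers of dropped rows are
#' attached as the \code{"drop_report"} attribute and reported via
#' \code{message()}.
#'
#' @param kb Source-species \code{mlr_kb}.
#' @param omap Named character vector (source symbol -> target symbol), a
#'   two-column data.frame, or a path readable by \code{\link{read_orthology}}.
#' @param target_species Target species, different from \code{kb$species}.
#' @return A new \code{mlr_kb} for \code{target_species} with attribute
#'   \code{drop_report} (named integer vector: interactions, enzymes,
#'   transporters).
#' @export
map_orthologs <- function(kb, omap, target_species) {
  stopifnot(inherits(kb, "mlr_kb"))
  target_species <- match.arg(target_species, KB_SPECIES)
  if (is.character(omap) && is.null(names(omap)) && length(omap) == 1L &&
      file.exists(omap)) {
    omap <- read_orthology(omap)
  }
  if (length(omap) == 0L)
    stop("map_orthologs: empty orthology map, nothing mappable", call. = FALSE)
  omap <- as_orthology_map(omap)
  if (identical(kb$species, target_species))
    stop("map_orthologs: target species equals KB species", call. = FALSE)

  map_one <- function(sym) unname(omap[sym])

  ia <- kb$interactions
  keep_ia <- logical(nrow(ia))
  new_receptor <- character(nrow(ia))
  if (nrow(ia)) for (i in seq_len(nrow(ia))) {
    subs <- receptor_subunits(ia$receptor[i])
    mapped <- map_one(subs)
    if (anyNA(mapped)) next
    keep_ia[i] <- TRUE
    new_receptor[i] <- paste(mapped, collapse = ";")
  }
  ia <- ia[keep_ia, , drop = FALSE]
  ia$receptor <- new_receptor[keep_ia]
  ia$species <- rep(target_species, nrow(ia))
  ia$receptor_canonical <- NULL

  ez <- kb$enzymes
  ez_new <- map_one(ez$gene)
  keep_ez <- !is.na(ez_new)
  ez <- ez[keep_ez, , drop = FALSE]
  ez$gene <- ez_new[keep_ez]

  tr <- kb$transporters
  tr_new <- map_one(tr$gene)
  keep_tr <- !is.na(tr_new)
  tr <- tr[keep_tr, , drop = FALSE]
  tr$gene <- tr_new[keep_tr]

  drop_report <- c(interactions = sum(!keep_ia), enzymes = sum(!keep_ez),
                   transporters = sum(!keep_tr))
  if (sum(drop_report) > 0L)
    message(sprintf("map_orthologs: dropped %d interaction(s), %d enzyme entr%s, %d transporter entr%s with unmapped symbols",
                    drop_report[["interactions"]],
                    drop_report[["enzymes"]],
                    if (drop_report[["enzymes"]] == 1L) "y" else "ies",
                    drop_report[["transporters"]],
                    if (drop_report[["transporters"]] == 1L) "y" else "ies"))

  out <- kb_create(target_species, kb$metabolites, ia, ez, tr, strict = FALSE)
  attr(out, "drop_report") <- drop_report
  out
}
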