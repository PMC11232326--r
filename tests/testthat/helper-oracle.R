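# Independent reference implementations used as oracles. Deliberately naive:
# plain loops, direct product-root geometric means, no shared code with the
# package internals.

gm_direct <- function(x) {
  if (length(x) == 0) return(0)
  prod(x)^(1 / length(x))
}

# Scalar re-derivation of the whole scoring pass: per-type means/fractions by
# explicit subsetting, filter by comparison, equations evaluated one by one.
# Returns rows only for triples whose receptor survives the receiver filter.
naive_reference <- function(expr, meta, kb, min_frac_pct = 10,
                            negative_e_policy = "literal",
                            include_autocrine = TRUE) {
  types <- sort(unique(unname(meta)))
  mean_of <- function(gene, type) {
    cells <- names(meta)[meta == type]
    mean(expr[gene, cells])
  }
  frac_of <- function(gene, type) {
    cells <- names(meta)[meta == type]
    mean(expr[gene, cells] > 0)
  }
  passes <- function(gene, type) {
    gene %in% rownames(expr) && frac_of(gene, type) * 100 >= min_frac_pct
  }
  ia <- kb$interactions
  ia <- ia[!duplicated(paste(ia$metabolite_id, ia$receptor_canonical)), ]
  rows <- list()
  for (s in types) for (r in types) {
    if (!include_autocrine && s == r) next
    for (i in seq_len(nrow(ia))) {
      mid <- ia$metabolite_id[i]
      subs <- strsplit(ia$receptor_canonical[i], ";", fixed = TRUE)[[1]]
      if (!all(vapply(subs, passes, logical(1), type = r))) next
      ez <- kb$enzymes[kb$enzymes$metabolite_id == mid, ]
      prod_g <- unique(ez$gene[ez$role %in% c("producer", "both")])
      cons_g <- unique(ez$gene[ez$role %in% c("consumer", "both")])
      tr_g <- unique(kb$transporters$gene[kb$transporters$metabolite_id == mid])
      prod_g <- prod_g[vapply(prod_g, passes, logical(1), type = s)]
      cons_g <- cons_g[vapply(cons_g, passes, logical(1), type = s)]
      tr_g <- tr_g[vapply(tr_g, passes, logical(1), type = s)]
      E <- gm_direct(vapply(prod_g, mean_of, numeric(1), type = s)) -
           gm_direct(vapply(cons_g, mean_of, numeric(1), type = s))
      Tv <- gm_direct(vapply(tr_g, mean_of, numeric(1), type = s))
      Ee <- if (negative_e_policy == "clamp") max(E, 0) else E
      M <- sqrt(Ee^2 + Tv^2)
      R <- gm_direct(vapply(subs, mean_of, numeric(1), type = r))
      rows[[length(rows) + 1]] <- data.frame(
        sender = s, receiver = r, metabolite_id = mid,
        receptor = ia$receptor_canonical[i],
        E = E, T = Tv, M = M, R = R, MR = sqrt(M^2 + R^2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# closed-form BH step-up, written straight from the definition
bh_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}
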