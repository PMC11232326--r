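# Hand-built single-interaction KB used for the chained-equation example:
# producers P1, P2; consumer C1; transporter TX1; receptor complex RA;RB.
tiny_kb <- function() {
  kb_create(
    species = "human",
    metabolites = data.frame(metabolite_id = "MET1", name = "tiny-metabolite",
                             stringsAsFactors = FALSE),
    interactions = data.frame(metabolite_id = "MET1", receptor = "RA;RB",
                              stringsAsFactors = FALSE),
    enzymes = data.frame(metabolite_id = "MET1",
                         gene = c("P1", "P2", "C1"),
                         role = c("producer", "producer", "consumer"),
                         stringsAsFactors = FALSE),
    transporters = data.frame(metabolite_id = "MET1", gene = "TX1",
                              stringsAsFactors = FALSE))
}

# One cell per type so per-type means equal the raw values. Sender "S"
# carries the enzyme/transporter values of the worked example, receiver "R"
# the receptor subunit values.
tiny_dataset <- function() {
  genes <- c("P1", "P2", "C1", "TX1", "RA", "RB")
  expr <- matrix(c(2, 8, 1, 4, 1, 1,     # cell s1 (type S)
                   1, 1, 1, 1, 2, 32),   # cell r1 (type R)
                 nrow = 6, dimnames = list(genes, c("s1", "r1")))
  meta <- c(s1 = "S", r1 = "R")
  list(expr = expr, meta = meta)
}

write_kb_fixture <- function(kb, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_kb(kb, dir)
  dir
}
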