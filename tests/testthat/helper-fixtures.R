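# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A tensor with explicit per-replicate alt counts at each locus.
# alt_counts: list (one per locus) of named vectors, e.g. list(c(G = 2)),
# recycled over replicates unless a matrix (replicates x bases) is given.
make_tensor <- function(depth, ref, alt_counts = NULL, n_rep = 3,
                        pos = NULL, chrom = "sim", sample = "S") {
  J <- length(ref)
  pos <- pos %||% seq_len(J)
  dm <- matrix(as.integer(depth), n_rep, J)
  counts <- array(0L, c(n_rep, J, 4), dimnames = list(NULL, NULL, c("A", "C", "G", "T")))
  for (j in seq_len(J)) {
    add <- integer(4)
    names(add) <- c("A", "C", "G", "T")
    if (!is.null(alt_counts) && length(alt_counts) >= j && !is.null(alt_counts[[j]]))
      add[names(alt_counts[[j]])] <- as.integer(alt_counts[[j]])
    for (n in seq_len(n_rep)) {
      counts[n, j, ] <- add
      counts[n, j, ref[j]] <- dm[n, j] - sum(add)
    }
  }
  read_count_tensor(counts, dm, pos = pos, ref = ref, chrom = chrom,
                    sample = sample)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Posterior objects with prescribed retained samples (for oracle tests of
# the somatic test and the point-estimate table).
make_posterior <- function(mu, pos, sample = "S") {
  poolvar:::new_vaf_posterior(mu, pos, sample = sample)
}

# Synthetic gene annotation matching the packaged fixture geometry:
# region chrXV:780367-782084, plus-strand CDS of 636 nt starting at 780867,
# with codon 63 = TCA and codon 209 = AAT.
make_annotation <- function(strand = "+") {
  set.seed(777)
  stops <- c("TAA", "TAG", "TGA")
  codons <- replicate(210, paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = ""))
  codons[codons %in% stops] <- "AAA"
  seqv <- c("ATG", codons, "TAA")
  seqv[63] <- "TCA"
  seqv[209] <- "AAT"
  cds <- paste(seqv, collapse = "")
  gene_annotation("chrXV", 780367, 782084, 780867, 781502, strand = strand,
                  cds_seq = cds, conserved = c(35, 63))
}
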