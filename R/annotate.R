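#' Gene annotation for a profiled amplicon region
#'
#' Describes the one gene inside the amplicon: the region, the CDS interval
#' within it, the strand, the coding (sense-strand) CDS sequence, and an
#' optional list of codon numbers conserved with a reference homologue
#' (e.g. residues aligned to the human enzyme). The CDS coordinates are a
#' required input rather than a packaged genome lookup.
#'
#' @param chrom chromosome label.
#' @param start,end region bounds, 1-based inclusive.
#' @param cds_start,cds_end CDS bounds within the region (genomic
#'   coordinates; for minus-strand genes `cds_start` is still the smaller
#'   genomic coordinate).
#' @param strand `"+"` or `"-"`.
#' @param cds_seq coding sequence, 5' to 3' on the coding strand; length
#'   must equal the CDS interval and be divisible by 3.
#' @param conserved integer codon numbers flagged as conserved.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(chrom, start, end, cds_start, cds_end,
                            strand = "+", cds_seq, conserved = integer(0)) {
  stopifnot(strand %in% c("+", "-"), start <= end)
  if (cds_start < start || cds_end > end || cds_start > cds_end)
    stop("CDS interval must lie within the region")
  cds_seq <- toupper(gsub("\\s", "", cds_seq))
  len <- cds_end - cds_start + 1L
  if (nchar(cds_seq) != len)
    stop(sprintf("CDS sequence length (%d) does not match the CDS interval (%d)",
                 nchar(cds_seq), len))
  if (len %% 3 != 0) stop("CDS length must be divisible by 3")
  if (grepl("[^ACGT]", cds_seq)) stop("CDS sequence contains non-ACGT characters")
  structure(list(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
                 strand = strand, cds_seq = cds_seq,
                 conserved = as.integer(conserved)),
            class = "gene_annotation")
}

#' Read a gene annotation from a YAML config file
#'
#' Fields: `chrom`, `start`, `end`, `cds_start`, `cds_end`, `strand`,
#' `conserved` (optional), and either `cds_seq` (inline) or `cds_fasta`
#' (path to a FASTA file, resolved relative to the config file).
#'
#' @param path YAML file path.
#' @return A [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  y <- yaml::read_yaml(path)
  seq <- y$cds_seq
  if (is.null(seq)) {
    if (is.null(y$cds_fasta)) stop("annotation needs cds_seq or cds_fasta")
    fa <- file.path(dirname(path), y$cds_fasta)
    if (!file.exists(fa)) fa <- y$cds_fasta
    seq <- as.character(Biostrings::readDNAStringSet(fa)[[1]])
  }
  gene_annotation(y$chrom, y$start, y$end, y$cds_start, y$cds_end,
                  strand = y$strand %||% "+", cds_seq = seq,
                  conserved = unlist(y$conserved) %||% integer(0))
}

#' Classify a position as promoter, CDS or terminator
#'
#' Deterministic partition of the region by CDS interval membership and
#' strand: positions upstream of the CDS on the coding strand are promoter,
#' downstream are terminator.
#'
#' @param pos genomic position(s) within the annotated region.
#' @param annotation a [gene_annotation()].
#' @return Character vector: `"promoter"`, `"CDS"` or `"terminator"`.
#' @export
classify_region <- function(pos, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (any(pos < annotation$start | pos > annotation$end))
    stop("position outside the annotated region")
  before <- pos < annotation$cds_start
  after <- pos > annotation$cds_end
  if (annotation$strand == "+") {
    ifelse(before, "promoter", ifelse(after, "terminator", "CDS"))
  } else {
    ifelse(after, "promoter", ifelse(before, "terminator", "CDS"))
  }
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

#' Amino-acid effect of a coding substitution
#'
#' Translates the reference and mutated codon containing CDS position
#' `cds_pos` with the standard genetic code and labels the substitution in
#' the conventional `<refAA><codon><altAA>` style (e.g. `"S63A"`), marking
#' synonymous changes.
#'
#' @param cds_pos 1-based position within the CDS (coding strand).
#' @param ref_base,alt_base reference and substituted base at that position,
#'   on the coding strand; `ref_base` must match the CDS sequence.
#' @param cds_seq the coding sequence.
#' @return A list with `label`, `codon` (number), `ref_aa`, `alt_aa`,
#'   `ref_codon`, `alt_codon` and `synonymous`.
#' @export
#' @examples
#' seq <- paste(rep("ATG", 100), collapse = "")
#' cds_effect(4, "A", "G", seq) # M2V
cds_effect <- function(cds_pos, ref_base, alt_base, cds_seq) {
  cds_seq <- toupper(gsub("\\s", "", cds_seq))
  if (cds_pos < 1 || cds_pos > nchar(cds_seq))
    stop("cds_pos outside the CDS")
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  have <- substr(cds_seq, cds_pos, cds_pos)
  if (have != ref_base)
    stop(sprintf("reference mismatch at CDS position %d: sequence has %s, call says %s",
                 cds_pos, have, ref_base))
  if (alt_base == ref_base) stop("alt base equals the reference base")
  if (!alt_base %in% DNA_BASES) stop("invalid alt base: ", alt_base)
  codon_no <- ((cds_pos - 1) %/% 3) + 1
  cstart <- 3 * (codon_no - 1) + 1
  ref_codon <- substr(cds_seq, cstart, cstart + 2)
  off <- cds_pos - cstart + 1
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt_base
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  list(label = sprintf("%s%d%s", ref_aa, codon_no, alt_aa),
       codon = codon_no, ref_aa = ref_aa, alt_aa = alt_aa,
       ref_codon = ref_codon, alt_codon = alt_codon,
       synonymous = ref_aa == alt_aa)
}

#' Annotate called variants with region class and coding consequence
#'
#' Adds to each call its region class (promoter/CDS/terminator) and, for CDS
#' positions, the CDS coordinate, codon number, amino-acid effect label and
#' conservation flag. Minus-strand genes are handled by complementing the
#' called bases and counting CDS positions from the genomic end of the CDS.
#'
#' @param calls a call table with columns `pos`, `ref` and `alt`.
#' @param annotation a [gene_annotation()].
#' @return The call table with added columns `region_class`, `cds_pos`,
#'   `codon`, `effect`, `synonymous` and `conserved`.
#' @export
annotate_calls <- function(calls, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  n <- nrow(calls)
  calls$region_class <- if (n) classify_region(calls$pos, annotation) else character(0)
  calls$cds_pos <- NA_integer_
  calls$codon <- NA_integer_
  calls$effect <- NA_character_
  calls$synonymous <- NA
  calls$conserved <- NA
  for (i in seq_len(n)) {
    if (calls$region_class[i] != "CDS") next
    if (annotation$strand == "+") {
      cp <- calls$pos[i] - annotation$cds_start + 1L
      rb <- calls$ref[i]; ab <- calls$alt[i]
    } else {
      cp <- annotation$cds_end - calls$pos[i] + 1L
      rb <- complement_base(calls$ref[i]); ab <- complement_base(calls$alt[i])
    }
    eff <- cds_effect(cp, rb, ab, annotation$cds_seq)
    calls$cds_pos[i] <- cp
    calls$codon[i] <- eff$codon
    calls$effect[i] <- eff$label
    calls$synonymous[i] <- eff$synonymous
    calls$conserved[i] <- eff$codon %in% annotation$conserved
  }
  calls
}

#' Timecourse matrix of VAF changes relative to the control timepoint
#'
#' The heatmap quantity of a selection screen: rows are the union of called
#' loci (ordered by position), columns are the non-control timepoints, and
#' each cell is `mu_hat_j(t) - mu_hat_j(T0)` (or the fold change
#' `mu_hat_j(t) / mu_hat_j(T0)` with `fold = TRUE`). The control-timepoint
#' estimate is attached as the attribute `baseline`. With an annotation,
#' row names carry the amino-acid effect and a conservation bullet.
#'
#' @param posteriors named list of [fit_vaf()] posteriors including the
#'   control.
#' @param positions loci to include (typically the call union).
#' @param control name of the control sample.
#' @param annotation optional [gene_annotation()] for row labelling.
#' @param fold report fold change instead of difference.
#' @param calls optional annotated call table (columns `pos`, `effect`,
#'   `conserved`) used for row labels instead of re-deriving them.
#' @return A numeric matrix `[positions x timepoints]` with attributes
#'   `baseline` (control VAF per row) and `positions`.
#' @export
vaf_change_matrix <- function(posteriors, positions, control = "T0",
                              annotation = NULL, fold = FALSE, calls = NULL) {
  stopifnot(control %in% names(posteriors))
  cases <- setdiff(names(posteriors), control)
  if (length(cases) < 1) stop("need at least one non-control timepoint")
  positions <- sort(unique(as.integer(positions)))
  ctrl <- posteriors[[control]]
  jidx <- match(positions, ctrl$pos)
  if (anyNA(jidx)) stop("positions absent from the fitted region")
  base <- ctrl$mu_hat[jidx]
  m <- vapply(cases, function(cs) {
    mu <- posteriors[[cs]]$mu_hat[match(positions, posteriors[[cs]]$pos)]
    if (fold) mu / base else mu - base
  }, numeric(length(positions)))
  m <- matrix(m, nrow = length(positions), ncol = length(cases),
              dimnames = list(as.character(positions), cases))
  labels <- as.character(positions)
  if (!is.null(annotation)) {
    ann_calls <- calls
    for (i in seq_along(positions)) {
      eff <- NA_character_; cons <- FALSE
      if (!is.null(ann_calls)) {
        hit <- ann_calls[ann_calls$pos == positions[i], , drop = FALSE]
        if (nrow(hit)) {
          eff <- hit$effect[1]
          cons <- isTRUE(hit$conserved[1])
        }
      }
      if (!is.na(eff))
        labels[i] <- sprintf("%d %s%s", positions[i], eff,
                             if (cons) " •" else "")
    }
    rownames(m) <- labels
  }
  attr(m, "baseline") <- setNames(base, rownames(m))
  attr(m, "positions") <- positions
  m
}

#' Plot a VAF-change matrix as a heatmap
#'
#' Thin wrapper around pheatmap with rows kept in positional order.
#'
#' @param m a [vaf_change_matrix()].
#' @param ... passed to [pheatmap::pheatmap()].
#' @export
plot_vaf_heatmap <- function(m, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_vaf_heatmap needs the pheatmap package")
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE, ...)
}
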