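#' Parse a region specification string
#'
#' @param spec a string `"chrom:start-end"`, 1-based inclusive.
#' @return A list with `chrom`, `start` and `end`.
#' @export
#' @examples
#' parse_region("chrXV:780367-782084")
parse_region <- function(spec) {
  m <- regmatches(spec, regexec("^([^:]+):([0-9]+)-([0-9]+)$", spec))[[1]]
  if (length(m) != 4) stop("malformed region: ", spec)
  out <- list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  if (out$end < out$start) stop("region end before start: ", spec)
  out
}

# Decode one pileup base string into per-base counts.
# '.'/',' reference match; ACGTacgt substitution; Nn ambiguous; '*' deletion
# placeholder and '<'/'>' reference skips count toward depth but toward no
# base; '^' (plus the following mapping-quality char) and '$' are read
# start/end markers; +N/-N introduce an indel sequence of N characters.
# Indels and read boundaries are consumed and excluded from SNV counts.
decode_pileup_bases <- function(s, line_no = NA) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cnt <- c(ref = 0L, A = 0L, C = 0L, G = 0L, T = 0L, other = 0L)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L              # skip the mapping quality character
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      if (j == i + 1L)
        stop(sprintf("malformed pileup indel at line %s", line_no))
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else if (ch == "." || ch == ",") {
      cnt["ref"] <- cnt["ref"] + 1L; i <- i + 1L
    } else if (toupper(ch) %in% DNA_BASES) {
      b <- toupper(ch)
      cnt[b] <- cnt[b] + 1L; i <- i + 1L
    } else if (ch %in% c("N", "n", "*", "<", ">")) {
      cnt["other"] <- cnt["other"] + 1L; i <- i + 1L
    } else {
      stop(sprintf("unexpected pileup character '%s' at line %s", ch, line_no))
    }
  }
  cnt
}

#' Parse samtools-style pileup text into a read count tensor
#'
#' Reads a pileup (one line per covered position: chrom, pos, ref, then one
#' depth/bases/qualities triple per replicate) and returns the count tensor
#' over the full requested region. Positions absent from the pileup get
#' depth 0. Every read present in the pileup is counted: base qualities are
#' ignored, indels and read start/end markers are consumed and excluded from
#' SNV counts, and N/deletion placeholders count toward depth but toward no
#' base (so they enter the non-reference count). Depth is recomputed from
#' the decoded symbols rather than trusted from the depth column.
#'
#' @param x a file path, or pileup text (a character vector of lines, or a
#'   single string with embedded newlines).
#' @param region a `"chrom:start-end"` string or a list as from
#'   [parse_region()].
#' @param sample sample label for the tensor.
#' @return A [read_count_tensor()] spanning the full region.
#' @export
parse_pileup <- function(x, region, sample = "S") {
  if (is.character(region)) region <- parse_region(region)
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(lines)]
  J <- region$end - region$start + 1L
  pos_all <- region$start + seq_len(J) - 1L

  N <- NULL
  per_line <- vector("list", length(lines))
  pos_seen <- integer(length(lines))
  ref_seen <- character(length(lines))
  keep <- logical(length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6 || (length(f) - 3) %% 3 != 0)
      stop(sprintf("malformed pileup line %d: expected 3 + 3k fields, got %d",
                   k, length(f)))
    nrep <- (length(f) - 3) %/% 3
    if (is.null(N)) N <- nrep
    else if (nrep != N)
      stop(sprintf("pileup line %d has %d replicates, expected %d", k, nrep, N))
    p <- suppressWarnings(as.integer(f[2]))
    if (is.na(p)) stop(sprintf("malformed pileup line %d: bad position '%s'", k, f[2]))
    if (f[1] != region$chrom || p < region$start || p > region$end) next
    if (!toupper(f[3]) %in% c(DNA_BASES, "N"))
      stop(sprintf("malformed pileup line %d: bad reference base '%s'", k, f[3]))
    per_line[[k]] <- lapply(seq_len(N), function(nn) {
      decode_pileup_bases(f[3 + 3 * (nn - 1) + 2], line_no = k)
    })
    pos_seen[k] <- p
    ref_seen[k] <- toupper(f[3])
    keep[k] <- TRUE
  }
  if (is.null(N)) N <- 1L
  if (anyDuplicated(pos_seen[keep]))
    stop("duplicate pileup positions within the region")

  depth <- matrix(0L, N, J)
  counts <- array(0L, c(N, J, 4), dimnames = list(NULL, NULL, DNA_BASES))
  ref <- rep("N", J)
  for (k in which(keep)) {
    j <- pos_seen[k] - region$start + 1L
    ref[j] <- ref_seen[k]
    for (nn in seq_len(N)) {
      cnt <- per_line[[k]][[nn]]
      base <- cnt[DNA_BASES]
      if (ref[j] %in% DNA_BASES)
        base[ref[j]] <- base[ref[j]] + cnt["ref"]
      counts[nn, j, ] <- base
      depth[nn, j] <- sum(cnt)   # ref + ACGT + ambiguous/deletion symbols
    }
  }
  read_count_tensor(counts, depth, pos_all, ref, chrom = region$chrom,
                    sample = sample, region = region)
}
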