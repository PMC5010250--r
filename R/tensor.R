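#' Per-replicate, per-locus read count tensor
#'
#' The container consumed by the model: for one sample (a timepoint or a
#' control), the sequencing depth and A/C/G/T base counts at every locus of
#' the region, for each technical replicate. Coordinates are 1-based
#' inclusive; the internal locus index j is the 0-based offset from the
#' region start. The non-reference count is derived as
#' `r_nj = d_nj - count(reference base)`, so reads counted toward depth but
#' toward no base (e.g. N calls in a pileup) count as non-reference.
#'
#' @param counts integer array `[n_replicates, loci, 4]`, bases ordered
#'   A, C, G, T.
#' @param depth integer matrix `[n_replicates, loci]`.
#' @param pos 1-based genomic position per locus (consecutive).
#' @param ref reference base per locus (`"N"` allowed for loci with no
#'   pileup evidence).
#' @param chrom chromosome label.
#' @param sample sample label.
#' @param region optional list `(chrom, start, end)`; defaults to the span
#'   of `pos`.
#' @return An object of class `read_count_tensor` with fields `region`,
#'   `pos`, `ref`, `depth`, `counts`, `nonref` and `sample`.
#' @export
read_count_tensor <- function(counts, depth, pos, ref, chrom = "chrXV",
                              sample = "S", region = NULL) {
  J <- length(pos)
  if (J > 0) {
    stopifnot(is.array(counts), length(dim(counts)) == 3, dim(counts)[3] == 4,
              is.matrix(depth), nrow(depth) == dim(counts)[1],
              ncol(depth) == J, dim(counts)[2] == J, length(ref) == J)
  }
  if (is.null(region)) {
    region <- list(chrom = chrom,
                   start = if (J) min(pos) else NA_integer_,
                   end = if (J) max(pos) else NA_integer_)
  }
  if (J > 0) {
    storage.mode(depth) <- "integer"
    storage.mode(counts) <- "integer"
  }
  obj <- structure(list(region = region, pos = as.integer(pos),
                        ref = toupper(ref),
                        depth = depth, counts = counts,
                        nonref = NULL, sample = sample),
                   class = "read_count_tensor")
  validate_tensor(obj)
}

validate_tensor <- function(x) {
  J <- length(x$pos)
  if (J == 0) {
    x$nonref <- matrix(integer(0), nrow = 0, ncol = 0)
    return(x)
  }
  if (any(x$counts < 0) || any(x$depth < 0))
    stop("negative counts or depths")
  base_sum <- apply(x$counts, c(1, 2), sum)
  if (any(base_sum > x$depth))
    stop("base counts exceed depth at some locus/replicate")
  bad_ref <- !x$ref %in% c(DNA_BASES, "N")
  if (any(bad_ref)) stop("invalid reference base: ", x$ref[which(bad_ref)[1]])
  ref_idx <- match(x$ref, DNA_BASES)
  ref_count <- matrix(0L, nrow(x$depth), J)
  known <- !is.na(ref_idx)
  for (j in which(known)) ref_count[, j] <- x$counts[, j, ref_idx[j]]
  x$nonref <- x$depth - ref_count
  if (any(x$nonref < 0 | x$nonref > x$depth))
    stop("non-reference counts out of [0, depth]")
  x
}

#' @export
print.read_count_tensor <- function(x, ...) {
  cat(sprintf("<read_count_tensor> sample %s: %s:%s-%s, %d loci x %d replicates\n",
              x$sample, x$region$chrom, x$region$start, x$region$end,
              length(x$pos), nrow(x$depth)))
  if (length(x$pos))
    cat(sprintf("  median depth %.0f, median non-ref rate %.2g\n",
                median(x$depth),
                median(x$nonref[x$depth > 0] / x$depth[x$depth > 0])))
  invisible(x)
}

#' Number of replicates in a tensor
#' @param x a `read_count_tensor`.
#' @export
n_replicates <- function(x) nrow(x$depth)

tensor_columns <- c("chrom", "pos", "ref", "depth",
                    "count_A", "count_C", "count_G", "count_T",
                    "replicate", "sample")

#' @export
as.data.frame.read_count_tensor <- function(x, ...) {
  N <- nrow(x$depth); J <- length(x$pos)
  if (J == 0 || N == 0)
    return(setNames(data.frame(matrix(ncol = 10, nrow = 0)), tensor_columns))
  data.frame(chrom = x$region$chrom,
             pos = rep(x$pos, each = N),
             ref = rep(x$ref, each = N),
             depth = as.vector(x$depth),
             count_A = as.vector(x$counts[, , "A"]),
             count_C = as.vector(x$counts[, , "C"]),
             count_G = as.vector(x$counts[, , "G"]),
             count_T = as.vector(x$counts[, , "T"]),
             replicate = rep(seq_len(N), times = J),
             sample = x$sample,
             stringsAsFactors = FALSE)
}

#' Write / read the package's tab-separated count-table dialect
#'
#' One row per (locus, replicate); columns chrom, pos, ref, depth, count_A,
#' count_C, count_G, count_T, replicate, sample. A `# region=` comment line
#' preserves the region so that an empty table round-trips losslessly.
#'
#' @param tensor a [read_count_tensor()].
#' @param path file path.
#' @export
write_count_table <- function(tensor, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# region=%s:%s-%s", tensor$region$chrom,
                     tensor$region$start, tensor$region$end), con)
  write.table(as.data.frame(tensor), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @return `read_count_table()` returns a [read_count_tensor()]; the
#'   write/read round trip is the identity on all fields.
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1)
  region <- NULL
  if (grepl("^# region=", first)) {
    spec <- sub("^# region=", "", first)
    if (grepl("^NA", sub("^[^:]+:", "", spec))) {
      region <- list(chrom = sub(":.*$", "", spec),
                     start = NA_integer_, end = NA_integer_)
    } else {
      region <- parse_region(spec)
    }
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(tensor_columns, names(df))
  if (length(missing))
    stop("count table is missing columns: ", paste(missing, collapse = ", "))
  cnt_cols <- c("depth", "count_A", "count_C", "count_G", "count_T")
  for (cc in cnt_cols) {
    v <- df[[cc]]
    if (nrow(df) && (!is.numeric(v) || anyNA(v) || any(v != as.integer(v))))
      stop("non-integer values in column ", cc)
  }
  if (nrow(df) == 0) {
    return(read_count_tensor(array(0L, c(0, 0, 4)),
                             matrix(0L, 0, 0), integer(0), character(0),
                             chrom = region$chrom %||% NA_character_,
                             sample = NA_character_, region = region))
  }
  pos <- sort(unique(df$pos))
  reps <- sort(unique(df$replicate))
  J <- length(pos); N <- length(reps)
  if (nrow(df) != J * N)
    stop("count table is not a complete locus x replicate grid")
  i <- match(df$replicate, reps)
  j <- match(df$pos, pos)
  depth <- matrix(0L, N, J)
  counts <- array(0L, c(N, J, 4), dimnames = list(NULL, NULL, DNA_BASES))
  depth[cbind(i, j)] <- as.integer(df$depth)
  for (b in DNA_BASES)
    counts[cbind(i, j, match(b, DNA_BASES))] <- as.integer(df[[paste0("count_", b)]])
  ref <- character(J)
  ref[j] <- df$ref
  read_count_tensor(counts, depth, pos, ref, chrom = df$chrom[1],
                    sample = df$sample[1], region = region)
}
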