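#' Fragment collections and the PAT dialect
#'
#' A fragment collection is the in-memory form of a PAT file: one row per
#' sequencing-read-level observation, holding the chromosome, the 0-based
#' index of the first covered CpG, the pattern of consecutive CpG calls
#' (`C` = methylated, `T` = unmethylated, `.` = missing), and a multiplicity
#' count. On disk (the PAT dialect) the start index is 1-based; the shift
#' happens only in [read_pat()]/[write_pat()].
#'
#' @param frags data.frame with columns `chrom`, `start_cpg` (0-based),
#'   `pattern`, `count`; an optional `origin` column is retained for
#'   mixture provenance validation.
#' @param provenance Label of the generating sample or cell type.
#' @param seed Seed used to generate the fragments (recorded, not used).
#' @param n_cpgs Size of the CpG index space the fragments live in
#'   (`NA` if unknown).
#' @return An object of class `fragment_collection` (a data.frame).
#' @export
fragment_collection <- function(frags, provenance = "unknown", seed = NA,
                                n_cpgs = NA) {
  stopifnot(is.data.frame(frags),
            all(c("chrom", "start_cpg", "pattern", "count") %in% names(frags)))
  if (nrow(frags) > 0) {
    if (any(frags$count < 1) || any(frags$count != floor(frags$count))) {
      stop("fragment counts must be integers >= 1")
    }
    if (any(!grepl("^[CT.]+$", frags$pattern))) {
      stop("fragment patterns must be non-empty strings over {C, T, .}")
    }
    if (any(frags$start_cpg < 0)) stop("fragment start indices must be >= 0")
    if (!is.na(n_cpgs) &&
        any(frags$start_cpg + nchar(frags$pattern) > n_cpgs)) {
      stop("fragment extends beyond the CpG map bound")
    }
  }
  frags$start_cpg <- as.integer(frags$start_cpg)
  frags$count <- as.integer(frags$count)
  structure(frags,
            provenance = provenance, seed = seed, n_cpgs = n_cpgs,
            class = c("fragment_collection", "data.frame"))
}

#' @export
print.fragment_collection <- function(x, ...) {
  cat(sprintf("Fragment collection '%s': %d records, %d fragments, %d CpG calls\n",
              attr(x, "provenance"), nrow(x), sum(x$count), n_calls(x)))
  if (!is.na(attr(x, "n_cpgs"))) {
    cat(sprintf("  CpG index space: %d sites (~%.2fx coverage)\n",
                attr(x, "n_cpgs"), n_calls(x) / attr(x, "n_cpgs")))
  }
  invisible(x)
}

#' Total number of observed (non-missing) CpG calls in a collection
#' @param x A [fragment_collection()].
#' @export
n_calls <- function(x) {
  if (nrow(x) == 0) return(0L)
  obs <- nchar(x$pattern) - nchar(gsub("[CT]", "", x$pattern))
  as.integer(sum(obs * x$count))
}

#' Read a PAT file
#'
#' Parses the 4-column tab-separated PAT dialect (chromosome, 1-based start
#' CpG index, pattern over `C`/`T`/`.`, count) into a fragment collection,
#' shifting start indices to the 0-based internal convention.
#'
#' @param path Path to a PAT file (plain or gzipped).
#' @param n_cpgs Optional CpG-universe size used for bound checking.
#' @return A [fragment_collection()].
#' @export
read_pat <- function(path, n_cpgs = NA) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(fragment_collection(
      data.frame(chrom = character(), start_cpg = integer(),
                 pattern = character(), count = integer()),
      provenance = basename(path), n_cpgs = n_cpgs))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad)) {
    stop(sprintf("malformed PAT line %d in '%s': expected 4 tab-separated fields",
                 bad[1], path))
  }
  m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  start_disk <- suppressWarnings(as.integer(m[, 2]))
  count <- suppressWarnings(as.integer(m[, 4]))
  bad <- which(is.na(start_disk) | start_disk < 1)
  if (length(bad)) stop(sprintf("malformed PAT line %d: bad start index", bad[1]))
  bad <- which(is.na(count) | count < 1)
  if (length(bad)) stop(sprintf("malformed PAT line %d: count must be an integer >= 1", bad[1]))
  bad <- which(!grepl("^[CT.]+$", m[, 3]))
  if (length(bad)) stop(sprintf("malformed PAT line %d: pattern must be over {C, T, .}", bad[1]))
  fragment_collection(
    data.frame(chrom = m[, 1], start_cpg = start_disk - 1L,
               pattern = m[, 3], count = count, stringsAsFactors = FALSE),
    provenance = basename(path), n_cpgs = n_cpgs)
}

#' Write a PAT file
#'
#' Writes a fragment collection as the 4-column PAT dialect, sorted by
#' (chromosome, start index, pattern) so output bytes are deterministic.
#' Internal 0-based start indices are shifted to the 1-based disk
#' convention. `read_pat(write_pat(x))` reproduces `x` up to record order.
#'
#' @param x A [fragment_collection()].
#' @param path Output path.
#' @param merge If `TRUE`, equal fragments at the same locus are merged by
#'   summing their counts (multiset semantics preserved).
#' @return `path`, invisibly.
#' @export
write_pat <- function(x, path, merge = FALSE) {
  stopifnot(inherits(x, "fragment_collection"))
  df <- data.frame(chrom = x$chrom, start = x$start_cpg + 1L,
                   pattern = x$pattern, count = x$count,
                   stringsAsFactors = FALSE)
  if (merge && nrow(df) > 0) {
    key <- paste(df$chrom, df$start, df$pattern, sep = "\r")
    cnt <- rowsum(df$count, key)
    first <- !duplicated(key)
    df <- df[first, ]
    df$count <- as.integer(cnt[match(paste(df$chrom, df$start, df$pattern, sep = "\r"),
                                     rownames(cnt)), 1])
  }
  df <- df[order(df$chrom, df$start, df$pattern, method = "radix"), ]
  con <- file(path, open = "wb")  # binary mode: identical bytes on any platform
  on.exit(close(con))
  if (nrow(df) > 0) {
    writeLines(paste(df$chrom, df$start, df$pattern, df$count, sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}

# Expand a collection into parallel call-level vectors, sorted by CpG index:
#   cpg  - 0-based CpG index of each observed call
#   meth - logical, TRUE when methylated
#   frag - integer fragment id (multiplicity expanded)
# Missing ('.') calls are dropped. This is the workhorse behind block
# tallies and U/X/M classification.
expand_calls <- function(x) {
  if (nrow(x) == 0) {
    return(list(cpg = integer(0), meth = logical(0), frag = integer(0),
                n_frags = 0L))
  }
  rep_idx <- rep.int(seq_len(nrow(x)), x$count)
  pat <- x$pattern[rep_idx]
  start <- x$start_cpg[rep_idx]
  len <- nchar(pat)
  codes <- utf8ToInt(paste(pat, collapse = ""))
  cpg <- rep.int(start, len) + (sequence(len) - 1L)
  frag <- rep.int(seq_along(pat), len)
  keep <- codes != 46L  # drop '.'
  cpg <- cpg[keep]; meth <- codes[keep] == 67L; frag <- frag[keep]
  o <- order(cpg, method = "radix")
  list(cpg = cpg[o], meth = meth[o], frag = frag[o], n_frags = length(pat))
}

# Per-CpG methylated/total call tallies over a CpG universe of size n.
per_cpg_tally <- function(x, n) {
  calls <- expand_calls(x)
  list(meth = tabulate(calls$cpg[calls$meth] + 1L, nbins = n),
       total = tabulate(calls$cpg + 1L, nbins = n))
}
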