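# Readers and writers for the external formats the pipeline touches.
# Every coordinate inside the package is 0-based half-open on the forward
# strand; BED/BEDPE are already in that convention so conversion happens
# nowhere else.

#' Read a FASTA file
#'
#' Loads a (multi-)FASTA file via [Biostrings::readDNAStringSet()] and
#' returns a named character vector of uppercase sequences. Only the
#' alphabet `{A,C,G,T,N}` is accepted.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one uppercase sequence per record, in
#'   file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stopf("FASTA parse error in %s: %s",
                                            path, conditionMessage(e)))
  if (length(set) == 0) stopf("FASTA parse error in %s: no records", path)
  seqs <- toupper(as.character(set))
  bad <- vapply(seqs, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    stopf("FASTA record '%s' contains characters outside {A,C,G,T,N}",
          names(seqs)[which(bad)[1]])
  }
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' BED is natively 0-based half-open, which is the package's internal
#' convention, so coordinates are kept as-is. Intervals are returned sorted
#' by `(chrom, start)`.
#'
#' @param path path to a tab-separated BED file (>= 3 columns, `#` comment
#'   lines ignored).
#' @param signal_column optional 0-based column index holding a numeric
#'   signal value (e.g. ChIP-seq enrichment); stored in the `signal`
#'   column.
#' @return data frame with columns `chrom`, `start`, `end`, `name`,
#'   `signal`.
#' @export
read_bed <- function(path, signal_column = NULL) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      signal = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3) stopf("BED line %d has fewer than 3 columns",
                          lineno[which.min(lengths(fields))])
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- as.integer(vapply(fields, `[[`, character(1), 2))
  end <- as.integer(vapply(fields, `[[`, character(1), 3))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0)
  if (length(bad)) {
    stopf("BED line %d: invalid interval (end <= start or negative start)",
          lineno[bad[1]])
  }
  name <- if (ncol_min >= 4) vapply(fields, `[[`, character(1), 4) else
    rep(NA_character_, length(chrom))
  signal <- rep(NA_real_, length(chrom))
  if (!is.null(signal_column)) {
    idx <- signal_column + 1L
    if (ncol_min < idx) stopf("signal_column %d not present in BED file",
                              signal_column)
    signal <- as.numeric(vapply(fields, `[[`, character(1), idx))
    if (any(!is.na(signal) & signal < 0)) stopf("negative signal in BED file")
  }
  df <- data.frame(chrom = chrom, start = start, end = end, name = name,
                   signal = signal, stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Write intervals as BED
#'
#' Emits `chrom start end name signal` (name/signal columns only when
#' present and non-NA anywhere).
#'
#' @param intervals data frame as returned by [read_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- list(intervals$chrom, intervals$start, intervals$end)
  if (!is.null(intervals$name) && any(!is.na(intervals$name))) {
    cols <- c(cols, list(ifelse(is.na(intervals$name), ".", intervals$name)))
    if (!is.null(intervals$signal) && any(!is.na(intervals$signal))) {
      cols <- c(cols, list(fmt_num(intervals$signal)))
    }
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BEDPE file of chromatin loops
#'
#' Each record is an ordered pair of anchors. Anchors are normalized so the
#' 5' anchor (lower genomic coordinate) comes first; inter-chromosomal
#' (trans) records are skipped with a warning since every analysis here is
#' cis. Columns beyond the seventh that parse as non-negative integers are
#' kept as per-sample counts `count_1..count_k`.
#'
#' @param path path to a tab-separated BEDPE file (>= 6 columns).
#' @return data frame of loops with columns `chrom`, `start5`, `end5`,
#'   `start3`, `end3`, `name`, `distance` (anchor midpoint separation, bp)
#'   and any `count_*` columns.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stopf("BEDPE file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  empty <- data.frame(chrom = character(), start5 = integer(),
                      end5 = integer(), start3 = integer(),
                      end3 = integer(), name = character(),
                      distance = numeric())
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (min(lengths(fields)) < 6) stopf("BEDPE requires >= 6 columns")
  c1 <- vapply(fields, `[[`, character(1), 1)
  s1 <- as.integer(vapply(fields, `[[`, character(1), 2))
  e1 <- as.integer(vapply(fields, `[[`, character(1), 3))
  c2 <- vapply(fields, `[[`, character(1), 4)
  s2 <- as.integer(vapply(fields, `[[`, character(1), 5))
  e2 <- as.integer(vapply(fields, `[[`, character(1), 6))
  trans <- c1 != c2
  if (any(trans)) {
    warnf("skipping %d inter-chromosomal (trans) BEDPE record(s)",
          sum(trans))
  }
  keep <- !trans
  if (!any(keep)) return(empty)
  fields <- fields[keep]
  c1 <- c1[keep]; s1 <- s1[keep]; e1 <- e1[keep]
  s2 <- s2[keep]; e2 <- e2[keep]
  name <- vapply(fields, function(f) if (length(f) >= 7) f[[7]] else
    NA_character_, character(1))
  # swap anchors so that the lower-coordinate anchor is the 5' anchor
  swap <- s1 > s2
  start5 <- ifelse(swap, s2, s1); end5 <- ifelse(swap, e2, e1)
  start3 <- ifelse(swap, s1, s2); end3 <- ifelse(swap, e1, e2)
  loops <- data.frame(chrom = c1, start5 = start5, end5 = end5,
                      start3 = start3, end3 = end3, name = name,
                      stringsAsFactors = FALSE)
  loops$distance <- abs(interval_mid(loops$start3, loops$end3) -
                          interval_mid(loops$start5, loops$end5))
  # optional trailing count columns (all-integer columns after col 7)
  extra <- max(lengths(fields)) - 7L
  if (extra > 0) {
    for (k in seq_len(extra)) {
      vals <- vapply(fields, function(f) {
        if (length(f) >= 7L + k) f[[7L + k]] else NA_character_
      }, character(1))
      num <- suppressWarnings(as.numeric(vals))
      if (all(!is.na(num) & num >= 0 & num == round(num))) {
        loops[[paste0("count_", k)]] <- as.integer(num)
      }
    }
  }
  rownames(loops) <- NULL
  loops
}

#' Write loops as BEDPE
#'
#' @param loops loop data frame as returned by [read_bedpe()]; extra
#'   columns given in `extra_cols` are appended after the name column.
#' @param path output path.
#' @param extra_cols character vector of additional column names of `loops`
#'   to write (e.g. orientation calls); count columns are always written.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path, extra_cols = character()) {
  nm <- if (is.null(loops$name)) rep(".", nrow(loops)) else
    ifelse(is.na(loops$name), ".", loops$name)
  cols <- list(loops$chrom, loops$start5, loops$end5,
               loops$chrom, loops$start3, loops$end3, nm)
  count_cols <- grep("^count_", names(loops), value = TRUE)
  for (cc in c(count_cols, extra_cols)) cols <- c(cols, list(loops[[cc]]))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Construct a contact matrix object
#'
#' A `contact_matrix` holds the symmetric binned count matrix for one
#' chromosome, with optional ICE-balanced layer, per-bin biases and a mask.
#'
#' @param chrom chromosome name.
#' @param bin_size bin size in bp (> 0).
#' @param counts symmetric non-negative numeric matrix.
#' @param balanced optional balanced layer (same dimensions).
#' @param biases optional per-bin multiplicative biases (NA where masked).
#' @param mask optional logical vector, `TRUE` for masked bins.
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, bin_size, counts, balanced = NULL,
                           biases = NULL, mask = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts), bin_size > 0)
  if (any(counts < 0)) stopf("contact matrix counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8)
    stopf("contact matrix must be symmetric")
  n <- nrow(counts)
  if (is.null(mask)) mask <- rep(FALSE, n)
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 n_bins = n, counts = counts, balanced = balanced,
                 biases = biases, mask = mask),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins of %d bp, total %g%s\n",
              x$chrom, x$n_bins, x$bin_size, sum(x$counts),
              if (is.null(x$balanced)) "" else ", balanced"))
  invisible(x)
}

#' Read a contact matrix in text COO format
#'
#' The format is a single `#`-prefixed header line `# chrom bin_size n_bins`
#' followed by tab-separated body lines `bin_i bin_j count` (0-based bin
#' indices). Records are mirrored into both triangles and duplicates are
#' summed.
#'
#' @param path path to the COO text file.
#' @return a [contact_matrix()].
#' @export
read_matrix_coo <- function(path) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^#", lines[1]))
    stopf("COO matrix must start with a '# chrom bin_size n_bins' header")
  hdr <- strsplit(sub("^#\\s*", "", lines[1]), "[ \t]+")[[1]]
  if (length(hdr) < 3) stopf("malformed COO header: %s", lines[1])
  chrom <- hdr[1]
  bin_size <- as.integer(hdr[2])
  n_bins <- as.integer(hdr[3])
  if (is.na(bin_size) || bin_size <= 0 || is.na(n_bins) || n_bins <= 0)
    stopf("malformed COO header: %s", lines[1])
  body <- lines[-1]
  body <- body[nzchar(body) & !grepl("^#", body)]
  counts <- matrix(0, n_bins, n_bins)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (min(lengths(parts)) < 3) stopf("COO body lines need 3 columns")
    i <- as.integer(vapply(parts, `[[`, character(1), 1))
    j <- as.integer(vapply(parts, `[[`, character(1), 2))
    v <- as.numeric(vapply(parts, `[[`, character(1), 3))
    if (any(is.na(i) | is.na(j) | is.na(v)))
      stopf("non-numeric COO body record")
    if (any(i < 0 | j < 0 | i >= n_bins | j >= n_bins))
      stopf("COO bin index out of range [0, %d)", n_bins)
    if (any(v < 0)) stopf("negative count in COO record")
    for (k in seq_along(i)) {
      counts[i[k] + 1L, j[k] + 1L] <- counts[i[k] + 1L, j[k] + 1L] + v[k]
      if (i[k] != j[k]) {
        counts[j[k] + 1L, i[k] + 1L] <- counts[j[k] + 1L, i[k] + 1L] + v[k]
      }
    }
  }
  contact_matrix(chrom, bin_size, counts)
}

#' Write a contact matrix in text COO format
#'
#' Writes the upper triangle (including the diagonal) of the raw counts.
#'
#' @param cm a [contact_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_coo <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  idx <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0,
               arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %d %d", cm$chrom, cm$bin_size, cm$n_bins), con)
  if (nrow(idx)) {
    writeLines(paste(idx[, 1] - 1L, idx[, 2] - 1L,
                     fmt_num(cm$counts[idx]), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a position weight matrix in minimal MEME text format
#'
#' Parses the first motif of a MEME-format file: `ALPHABET= ACGT`, an
#' optional `Background letter frequencies` block, and one
#' `letter-probability matrix` block. A pseudocount is added and positions
#' renormalized so that all probabilities are strictly positive.
#'
#' @param path path to the MEME text file.
#' @param pseudocount probability mass added to every cell before
#'   renormalization (default 0.01).
#' @return an object of class `pwm`: list with `name`, `probs` (4 x K
#'   matrix, rows A,C,G,T), `background` (length-4), `length`.
#' @export
read_meme_motif <- function(path, pseudocount = 0.01) {
  if (!file.exists(path)) stopf("motif file not found: %s", path)
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1L]), "[ \t]+")[[1]]
    if (length(toks) >= 8) {
      vals <- as.numeric(toks[seq(2, 8, by = 2)])
      names(vals) <- toks[seq(1, 7, by = 2)]
      bg <- vals[c("A", "C", "G", "T")]
      if (any(is.na(bg)) || abs(sum(bg) - 1) > 1e-3)
        stopf("malformed background line in %s", path)
    }
  }
  mot_i <- grep("^MOTIF", lines)
  if (!length(mot_i)) stopf("no MOTIF block in %s", path)
  name <- strsplit(trimws(lines[mot_i[1]]), "[ \t]+")[[1]][2]
  lpm_i <- grep("^letter-probability matrix", lines)
  if (!length(lpm_i)) stopf("no letter-probability matrix in %s", path)
  rows <- list()
  k <- lpm_i[1] + 1L
  while (k <= length(lines)) {
    toks <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) != 4 || any(is.na(vals))) break
    rows[[length(rows) + 1L]] <- vals
    k <- k + 1L
  }
  if (length(rows) < 4) stopf("PWM in %s must have K >= 4 positions", path)
  probs <- t(do.call(rbind, rows))  # 4 x K, rows A,C,G,T
  sums <- colSums(probs)
  if (any(abs(sums - 1) > 1e-3))
    stopf("PWM position %d does not sum to 1 (got %.4f)",
          which(abs(sums - 1) > 1e-3)[1], sums[which(abs(sums - 1) > 1e-3)[1]])
  new_pwm(name, probs, bg, pseudocount = pseudocount)
}

#' Construct a PWM object
#'
#' @param name motif label.
#' @param probs 4 x K probability matrix, rows in A,C,G,T order.
#' @param background length-4 background base probabilities (A,C,G,T).
#' @param pseudocount added to every cell then positions renormalized;
#'   guarantees strictly positive probabilities.
#' @return object of class `pwm`.
#' @export
new_pwm <- function(name, probs, background = rep(0.25, 4),
                    pseudocount = 0.01) {
  stopifnot(is.matrix(probs), nrow(probs) == 4, ncol(probs) >= 1)
  background <- as.numeric(background)
  stopifnot(length(background) == 4, all(background > 0))
  background <- background / sum(background)
  probs <- probs + pseudocount
  probs <- sweep(probs, 2, colSums(probs), "/")
  rownames(probs) <- ALPHABET
  structure(list(name = name, probs = probs, background = background,
                 length = ncol(probs)),
            class = "pwm")
}

#' Build a sharp PWM from a consensus word
#'
#' Each position puts probability `1 - 3 * off` on the consensus base and
#' `off` on each other base. Handy for synthetic scenarios and tests.
#'
#' @param consensus word over `{A,C,G,T}`.
#' @param off per-position probability of each non-consensus base
#'   (default 0.01).
#' @param name motif label (default the consensus itself).
#' @param background length-4 background probabilities.
#' @return a `pwm`.
#' @export
pwm_from_consensus <- function(consensus, off = 0.01, name = consensus,
                               background = rep(0.25, 4)) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% ALPHABET))
  probs <- matrix(off, 4, length(bases), dimnames = list(ALPHABET, NULL))
  for (k in seq_along(bases)) probs[bases[k], k] <- 1 - 3 * off
  new_pwm(name, probs, background, pseudocount = 0)
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(ALPHABET[apply(x$probs, 2, which.max)], collapse = "")
  cat(sprintf("pwm '%s': %d positions, consensus %s\n",
              x$name, x$length, cons))
  invisible(x)
}

#' Consensus word of a PWM
#'
#' @param pwm a `pwm`.
#' @return character scalar: the highest-probability base at each position.
#' @export
pwm_consensus <- function(pwm) {
  paste(ALPHABET[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Write a PWM in minimal MEME text format
#'
#' @param pwm a `pwm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme_motif <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       pwm$background[1], pwm$background[2],
                       pwm$background[3], pwm$background[4]),
               "",
               sprintf("MOTIF %s", pwm$name),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       pwm$length)), con)
  writeLines(apply(pwm$probs, 2, function(p)
    sprintf("%.6f %.6f %.6f %.6f", p[1], p[2], p[3], p[4])), con)
  invisible(path)
}
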