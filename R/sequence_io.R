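#' Construct a validated promoter sequence
#'
#' A `promoter_sequence` is a plain A/C/G/T nucleotide string with optional
#' bookkeeping: the 1-based position of the 'A' of the translation-start ATG
#' (used to label sites with the conventional signed coordinates -1, +1, ...
#' with no position 0, +1 at the ATG).
#'
#' @param id Record identifier.
#' @param bases Nucleotide string. Lowercase is accepted and 'U' is mapped to
#'   'T'; any other symbol (including 'N' and IUPAC ambiguity codes) is
#'   rejected with the offending position, since downstream physics requires
#'   a deterministic A-T / G-C classification of every site.
#' @param atg_pos Optional 1-based index of the 'A' of the start codon.
#' @return An object of class `promoter_sequence`.
#' @examples
#' s <- promoter_sequence("toy", "acguACGT")
#' s$bases
#' @export
promoter_sequence <- function(id, bases, atg_pos = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(bases), length(bases) == 1L)
  b <- chartr("u", "t", tolower(bases))
  b <- toupper(b)
  ch <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(ch) == 0L) stop("sequence '", id, "' is empty")
  bad <- which(!(ch %in% c("A", "C", "G", "T")))
  if (length(bad) > 0L)
    stop("sequence '", id, "' contains invalid symbol '", ch[bad[1]],
         "' at position ", bad[1],
         " (only A/C/G/T/U accepted; ambiguity codes such as N are rejected)")
  if (!is.null(atg_pos)) {
    atg_pos <- as.integer(atg_pos)
    if (atg_pos < 1L || atg_pos > length(ch))
      stop("atg_pos must lie within the sequence (1..", length(ch), ")")
  }
  structure(list(id = id, bases = paste(ch, collapse = ""),
                 atg_pos = atg_pos),
            class = "promoter_sequence")
}

#' @export
print.promoter_sequence <- function(x, ...) {
  n <- nchar(x$bases)
  cat(sprintf("promoter_sequence '%s': %d bp, A-T content %.1f%%%s\n",
              x$id, n, 100 * at_content(x),
              if (is.null(x$atg_pos)) "" else
                sprintf(", ATG at %d", x$atg_pos)))
  invisible(x)
}

#' Read promoter sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file and validates every record. 'U' is
#' mapped to 'T' and case is normalized; 'N' or any ambiguity code raises an
#' error naming the record and position.
#'
#' @param path Path to a FASTA file.
#' @param atg_pos Optional vector of ATG anchor positions, recycled across
#'   records (or a single value, or NULL).
#' @return A list of [promoter_sequence()] objects in file order.
#' @export
read_promoter_fasta <- function(path, atg_pos = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- names(set)
  if (is.null(ids)) ids <- paste0("seq", seq_along(set))
  ids <- sub("\\s.*$", "", ids)
  anchors <- if (is.null(atg_pos)) vector("list", length(set))
             else as.list(rep_len(atg_pos, length(set)))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- promoter_sequence(ids[i], as.character(set[[i]]),
                                  atg_pos = anchors[[i]])
  }
  out
}

#' Write promoter sequences to FASTA (with optional ground-truth sidecar)
#'
#' @param seqs A `promoter_sequence` or list of them.
#' @param path Output FASTA path.
#' @param sidecar Optional path for a JSON sidecar recording the planted
#'   soft-window ground truth of synthetic sequences (see
#'   [synth_promoter()]).
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(seqs, path, sidecar = NULL) {
  if (inherits(seqs, "promoter_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$bases, ""))
  names(set) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(set, path)
  if (!is.null(sidecar)) {
    gt <- lapply(seqs, function(s) {
      w <- attr(s, "windows")
      list(id = s$id,
           atg_pos = s$atg_pos,
           windows = if (is.null(w)) list() else w)
    })
    jsonlite::write_json(gt, sidecar, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' A-T fraction of a promoter sequence
#'
#' @param seq A [promoter_sequence()].
#' @return `(#A + #T) / length`, a number in `[0, 1]`. Boundary clamps are
#'   never part of a `promoter_sequence`, so they are automatically excluded.
#' @export
at_content <- function(seq) {
  stopifnot(inherits(seq, "promoter_sequence"))
  ch <- strsplit(seq$bases, "", fixed = TRUE)[[1]]
  if (length(ch) == 0L) stop("empty sequence")
  mean(ch %in% c("A", "T"))
}

#' Encode a promoter sequence as a simulated chain
#'
#' Maps each base to its pair class (A-T soft, G-C stiff), appends `clamp_len`
#' G-C clamp pairs at each end (held closed during dynamics to avoid end
#' effects), and records the analysis mask (non-clamp sites) together with
#' two coordinate systems: the plain 1-based sequence position and, when an
#' ATG anchor is present, signed genomic labels (..., -2, -1, +1, +2, ...,
#' +1 at the 'A' of ATG, no label 0).
#'
#' @param seq A [promoter_sequence()].
#' @param clamp_len Number of G-C clamp pairs added per end (default 10).
#' @return An object of class `encoded_chain` with elements `pair_class`
#'   ("AT"/"GC" per simulated site), `is_clamp`, `mask`, `seq_position`
#'   (NA at clamps), `position_labels` (NA at clamps or without anchor),
#'   `N`, `n_seq`, `clamp_len`, `id`, `atg_pos`.
#' @export
encode_chain <- function(seq, clamp_len = 10L) {
  stopifnot(inherits(seq, "promoter_sequence"))
  clamp_len <- as.integer(clamp_len)
  if (clamp_len < 0L) stop("clamp_len must be >= 0")
  ch <- strsplit(seq$bases, "", fixed = TRUE)[[1]]
  n_seq <- length(ch)
  core <- ifelse(ch %in% c("A", "T"), "AT", "GC")
  pair_class <- c(rep("GC", clamp_len), core, rep("GC", clamp_len))
  N <- n_seq + 2L * clamp_len
  is_clamp <- c(rep(TRUE, clamp_len), rep(FALSE, n_seq), rep(TRUE, clamp_len))
  seq_position <- rep(NA_integer_, N)
  seq_position[!is_clamp] <- seq_len(n_seq)
  position_labels <- rep(NA_integer_, N)
  if (!is.null(seq$atg_pos)) {
    i <- seq_len(n_seq)
    lab <- ifelse(i >= seq$atg_pos, i - seq$atg_pos + 1L, i - seq$atg_pos)
    position_labels[!is_clamp] <- as.integer(lab)
  }
  structure(list(pair_class = pair_class, is_clamp = is_clamp,
                 mask = !is_clamp, seq_position = seq_position,
                 position_labels = position_labels,
                 N = N, n_seq = n_seq, clamp_len = clamp_len,
                 id = seq$id, atg_pos = seq$atg_pos),
            class = "encoded_chain")
}

#' @export
print.encoded_chain <- function(x, ...) {
  cat(sprintf(
    "encoded_chain '%s': %d sites (%d bp + 2 x %d G-C clamps), %d A-T sites\n",
    x$id, x$N, x$n_seq, x$clamp_len, sum(x$pair_class == "AT" & x$mask)))
  invisible(x)
}

# per-site Morse parameters for an encoded chain
site_morse <- function(chain, params) {
  at <- chain$pair_class == "AT"
  list(D = ifelse(at, params$D_AT, params$D_GC),
       a = ifelse(at, params$a_AT, params$a_GC))
}

#' Generate a synthetic promoter-like sequence
#'
#' Draws a random A/C/G/T string in which the per-site probability of an A or
#' T equals `background_at` outside the given windows and each window's own
#' A-T fraction inside. A-T-rich windows emulate the "soft" easily-opening
#' regions around transcription start sites; the planted window coordinates
#' are attached as ground truth for benchmarking site recovery.
#'
#' @param length Sequence length (bp).
#' @param background_at Background A-T fraction in `[0, 1]`.
#' @param windows Ground-truth soft windows: a data.frame (or list coercible
#'   to one) with columns `start` (1-based), `width`, `at` (window A-T
#'   fraction). Windows must lie within the sequence and must not overlap.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param id Record id.
#' @param atg_pos Optional ATG anchor position.
#' @return A [promoter_sequence()] with the windows data.frame attached as
#'   attribute `"windows"`.
#' @examples
#' s <- synth_promoter(300, 0.4,
#'                     windows = data.frame(start = 150, width = 30, at = 0.95),
#'                     seed = 42)
#' attr(s, "windows")
#' @export
synth_promoter <- function(length, background_at, windows = NULL, seed = 1L,
                           id = "synthetic", atg_pos = NULL) {
  length <- as.integer(length)
  if (length < 1L) stop("length must be >= 1")
  if (background_at < 0 || background_at > 1)
    stop("background_at must be in [0, 1]")
  if (!is.null(windows)) {
    windows <- as.data.frame(windows)
    stopifnot(all(c("start", "width", "at") %in% names(windows)))
    if (any(windows$at < 0 | windows$at > 1))
      stop("window A-T fractions must be in [0, 1]")
    if (any(windows$start < 1 | windows$start + windows$width - 1 > length))
      stop("windows must lie within the sequence")
    if (nrow(windows) > 1L) {
      o <- order(windows$start)
      w <- windows[o, ]
      ends <- w$start + w$width - 1
      if (any(w$start[-1] <= ends[-nrow(w)])) stop("windows overlap")
    }
  }
  p_at <- rep(background_at, length)
  if (!is.null(windows)) {
    for (i in seq_len(nrow(windows))) {
      idx <- windows$start[i]:(windows$start[i] + windows$width[i] - 1)
      p_at[idx] <- windows$at[i]
    }
  }
  ch <- withr::with_seed(as.integer(seed), {
    is_at <- stats::runif(length) < p_at
    ifelse(is_at,
           ifelse(stats::runif(length) < 0.5, "A", "T"),
           ifelse(stats::runif(length) < 0.5, "G", "C"))
  })
  out <- promoter_sequence(id, paste(ch, collapse = ""), atg_pos = atg_pos)
  attr(out, "windows") <- windows
  out
}
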