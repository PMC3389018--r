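#' Reverse complement of DNA sequences
#'
#' Vectorized over inputs; alphabet ACGTN, case-insensitive in, uppercase
#' out. An inverted-repeat core is its own reverse complement.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements (uppercase).
#' @export
#' @examples
#' reverse_complement("TTGTGCACAA")  # a perfect inverted repeat
reverse_complement <- function(seq) {
  up <- toupper(seq)
  if (any(grepl("[^ACGTN]", up))) {
    abort_ferm("sequences may only contain A, C, G, T, N", "validation")
  }
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", up))
}

#' Extract upstream (promoter) regions
#'
#' Uses 0-based half-open gene coordinates: a + strand gene at `[start, end)`
#' yields the forward-strand bases `[start - length, start)`; a - strand
#' gene yields the reverse complement of `[end, end + length)`. Regions
#' running off a contig edge are truncated and flagged.
#'
#' @param coords Tibble/data frame with columns `gene_id`, `seqname`
#'   (contig; optional when the genome has a single sequence), `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`).
#' @param genome Named character vector of contig sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param length Upstream length in bp (default 300).
#' @return Tibble `gene_id`, `seq`, `truncated`.
#' @export
extract_upstream <- function(coords, genome, length = 300) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  coords <- as_tibble(coords)
  if (!"seqname" %in% names(coords)) {
    if (base::length(genome) != 1) {
      abort_ferm("coords need a 'seqname' column for a multi-contig genome", "format")
    }
    coords$seqname <- names(genome)[1] %||% "contig1"
    if (is.null(names(genome))) names(genome) <- coords$seqname[1]
  }
  missing <- setdiff(coords$seqname, names(genome))
  if (base::length(missing)) {
    abort_ferm(paste0("contig absent from genome: ", missing[1]), "key")
  }
  if (!all(coords$strand %in% c("+", "-"))) {
    abort_ferm("strand must be '+' or '-'", "validation")
  }
  rows <- purrr::pmap(coords[, c("gene_id", "seqname", "start", "end", "strand")],
                      function(gene_id, seqname, start, end, strand) {
    ctg <- genome[[seqname]]
    L <- nchar(ctg)
    if (strand == "+") {
      lo <- max(0L, start - length); hi <- start
      s <- substr(ctg, lo + 1L, hi)
    } else {
      lo <- end; hi <- min(L, end + length)
      s <- reverse_complement(substr(ctg, lo + 1L, hi))
    }
    tibble(gene_id = gene_id, seq = toupper(s),
           truncated = (hi - lo) < length)
  })
  dplyr::bind_rows(rows)
}

# Coerce promoters given as a named character vector, DNAStringSet or tibble
# (gene_id, seq) to a named uppercase character vector.
as_promoter_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    return(stats::setNames(toupper(as.character(x)), names(x)))
  }
  if (is.data.frame(x)) return(stats::setNames(toupper(x$seq), x$gene_id))
  out <- toupper(x)
  if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  out
}

# All realized inverted repeats (arm + spacer + revcomp(arm)) in one
# sequence, for the given arm and spacer ranges. Returns a tibble of
# candidate keys with first-occurrence offsets (0-based).
realized_irs <- function(seq, arm_range, spacer_range) {
  L <- nchar(seq)
  rows <- list()
  for (k in seq(arm_range[1], arm_range[2])) {
    n_pos <- L - k + 1L
    if (n_pos < 1) next
    kmers <- substring(seq, seq_len(n_pos), seq_len(n_pos) + k - 1L)
    rc <- reverse_complement(kmers)
    for (sp in seq(spacer_range[1], spacer_range[2])) {
      i <- seq_len(max(0L, L - (2L * k + sp) + 1L))
      if (!base::length(i)) next
      hit <- kmers[i + k + sp] == rc[i] & !grepl("N", kmers[i], fixed = TRUE)
      if (any(hit)) {
        w <- i[hit]
        rows[[base::length(rows) + 1L]] <-
          tibble(arm = kmers[w], spacer = sp, offset = w - 1L)
      }
    }
  }
  if (!base::length(rows)) {
    return(tibble(arm = character(), spacer = integer(), offset = integer()))
  }
  dplyr::bind_rows(rows)
}

#' Discover enriched inverted-repeat motifs
#'
#' Enumerates every inverted repeat (arm + spacer + reverse-complement arm)
#' realized in the foreground promoters, counts the promoters containing
#' each candidate (an inverted repeat is strand-symmetric, so forward-strand
#' scanning finds sites planted on either strand), and scores foreground
#' enrichment by the upper-tail hypergeometric p of foreground presence
#' within foreground + background. Candidates present in at least
#' `min_fg_fraction` of foreground promoters are reported ranked by p (ties:
#' wider motifs first); near-duplicate candidates whose promoter sets
#' overlap with Jaccard > `merge_jaccard` are merged into their best-scoring
#' representative. Each reported motif carries its site list, a
#' position-weight matrix built from the aligned sites with +0.5
#' pseudocounts, and per-column information content.
#'
#' @param foreground,background Promoter sets (named character vector,
#'   tibble with `gene_id`/`seq`, or `DNAStringSet`); both non-empty.
#' @param arm_range Arm lengths in bp, `c(min, max)` (default 4-7; minimum
#'   allowed 3).
#' @param spacer_range Spacer lengths in bp (default 0-6).
#' @param min_fg_fraction Minimum foreground presence fraction (default 0.3).
#' @param merge_jaccard Site-set Jaccard above which overlapping candidates
#'   collapse (default 0.8).
#' @return A list of class `motif_set` of `motif_model` objects, best first;
#'   `tidy()` gives the summary table.
#' @export
find_inverted_repeats <- function(foreground, background,
                                  arm_range = c(4, 7), spacer_range = c(0, 6),
                                  min_fg_fraction = 0.3, merge_jaccard = 0.8) {
  if (arm_range[1] < 3) {
    abort_ferm("arm lengths below 3 give degenerate repeats", "config")
  }
  fg <- as_promoter_set(foreground)
  bg <- as_promoter_set(background)
  if (!base::length(fg) || !base::length(bg)) {
    abort_ferm("foreground and background must be non-empty", "validation")
  }

  scan_set <- function(seqs) {
    purrr::imap(seqs, function(s, id) {
      ir <- realized_irs(s, arm_range, spacer_range)
      ir$seq_id <- rep(id, nrow(ir))
      ir
    })
  }
  fg_ir <- dplyr::bind_rows(scan_set(fg))
  bg_ir <- dplyr::bind_rows(scan_set(bg))
  if (nrow(fg_ir) == 0) {
    return(structure(list(), class = "motif_set",
                     n_fg = base::length(fg), n_bg = base::length(bg)))
  }
  fg_ir$key <- paste0(fg_ir$arm, "|", fg_ir$spacer)
  bg_ir$key <- if (nrow(bg_ir)) paste0(bg_ir$arm, "|", bg_ir$spacer) else character()

  n_fg <- base::length(fg); n_bg <- base::length(bg); N <- n_fg + n_bg
  fg_pres <- fg_ir %>% dplyr::distinct(.data$key, .data$seq_id)
  bg_pres <- bg_ir %>% dplyr::distinct(.data$key, .data$seq_id)
  k_fg <- table(fg_pres$key)
  k_bg <- table(bg_pres$key)

  cand <- tibble(key = names(k_fg), k_fg = as.integer(k_fg))
  cand$k_bg <- as.integer(k_bg[cand$key]); cand$k_bg[is.na(cand$k_bg)] <- 0L
  cand <- cand[cand$k_fg / n_fg >= min_fg_fraction, ]
  if (nrow(cand) == 0) {
    return(structure(list(), class = "motif_set", n_fg = n_fg, n_bg = n_bg))
  }
  cand$p <- stats::phyper(cand$k_fg - 1L, cand$k_fg + cand$k_bg,
                          N - (cand$k_fg + cand$k_bg), n_fg, lower.tail = FALSE)
  cand$q <- bh_fdr(cand$p)
  cand$arm <- sub("\\|.*$", "", cand$key)
  cand$spacer <- as.integer(sub("^.*\\|", "", cand$key))
  cand$width <- 2L * nchar(cand$arm) + cand$spacer
  cand <- cand[order(cand$p, -cand$width, cand$arm), ]

  # merge shifted/nested variants of the same repeat
  sets <- split(fg_pres$seq_id, fg_pres$key)
  kept <- list()
  for (i in seq_len(nrow(cand))) {
    s_i <- sets[[cand$key[i]]]
    dup <- FALSE
    for (kp in kept) {
      jac <- base::length(intersect(s_i, kp$set)) / base::length(union(s_i, kp$set))
      if (jac > merge_jaccard) { dup <- TRUE; break }
    }
    if (!dup) kept[[base::length(kept) + 1L]] <- list(row = i, set = s_i)
  }

  models <- lapply(kept, function(kp) {
    i <- kp$row
    sites_fg <- fg_ir[fg_ir$key == cand$key[i], ]
    sites_bg <- bg_ir[nrow(bg_ir) > 0 & bg_ir$key == cand$key[i], ]
    sites <- dplyr::bind_rows(
      tibble(seq_id = sites_fg$seq_id, offset = sites_fg$offset,
             strand = "+", set = "foreground"),
      if (nrow(sites_bg)) tibble(seq_id = sites_bg$seq_id,
                                 offset = sites_bg$offset,
                                 strand = "+", set = "background")
    )
    all_seqs <- c(fg, bg)
    sites$match <- substring(all_seqs[sites$seq_id], sites$offset + 1L,
                             sites$offset + cand$width[i])
    pwm <- build_pwm(sites$match, pseudocount = 0.5)
    spacer_cons <- if (cand$spacer[i] > 0) {
      paste0(c("A", "C", "G", "T")[apply(
        pwm[, nchar(cand$arm[i]) + seq_len(cand$spacer[i]), drop = FALSE],
        2, which.max)], collapse = "")
    } else ""
    structure(list(arm = cand$arm[i], spacer_len = cand$spacer[i],
                   arm_len = nchar(cand$arm[i]), width = cand$width[i],
                   consensus = paste0(cand$arm[i], spacer_cons,
                                      reverse_complement(cand$arm[i])),
                   sites = sites, pwm = pwm,
                   ic = pwm_information_content(pwm),
                   k_fg = cand$k_fg[i], k_bg = cand$k_bg[i],
                   n_fg = n_fg, n_bg = n_bg,
                   p_value = cand$p[i], q_value = cand$q[i]),
              class = "motif_model")
  })
  structure(models, class = "motif_set", n_fg = n_fg, n_bg = n_bg)
}

#' Build a position-weight matrix from aligned sites
#'
#' @param sites Character vector of equal-length aligned site sequences.
#' @param pseudocount Added to every base count (default 0.5).
#' @return A 4 x width column-stochastic matrix (rows A, C, G, T).
#' @export
build_pwm <- function(sites, pseudocount = 0.5) {
  stopifnot(base::length(sites) > 0, base::length(unique(nchar(sites))) == 1)
  w <- nchar(sites[1])
  mat <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  chars <- matrix(unlist(strsplit(toupper(sites), "")), ncol = w, byrow = TRUE)
  for (j in seq_len(w)) {
    cnt <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
    mat[, j] <- (as.numeric(cnt) + pseudocount)
  }
  sweep(mat, 2, colSums(mat), "/")
}

#' Per-column information content of a PWM (bits, uniform background)
#'
#' @param pwm A 4 x width column-stochastic matrix.
#' @return Numeric vector, one value in \[0, 2\] per column.
#' @export
pwm_information_content <- function(pwm) {
  apply(pwm, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Scan sequences with a PWM
#'
#' Log-odds scan (uniform background) of both strands; windows scoring at
#' least `score_threshold` times the maximum attainable score are reported.
#' Windows containing `N` never match; sequences shorter than the PWM are
#' skipped with a warning.
#'
#' @param motif A `motif_model` or a raw 4 x width PWM.
#' @param sequences A promoter set (named character vector, tibble,
#'   `DNAStringSet`).
#' @param score_threshold Fraction of the maximum log-odds score (default
#'   0.9).
#' @return Tibble of hits: `seq_id`, `offset` (0-based), `strand`, `score`.
#' @export
scan_motif <- function(motif, sequences, score_threshold = 0.9) {
  pwm <- if (inherits(motif, "motif_model")) motif$pwm else motif
  stopifnot(is.matrix(pwm), nrow(pwm) == 4)
  seqs <- as_promoter_set(sequences)
  lo <- log2(pwm / 0.25)
  w <- ncol(lo)
  max_score <- sum(apply(lo, 2, max))
  thr <- score_threshold * max_score

  score_one <- function(s) {
    L <- nchar(s)
    if (L < w) return(NULL)
    idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    n_win <- L - w + 1L
    sc <- rep(0, n_win)
    for (j in seq_len(w)) {
      col <- lo[, j][idx[seq_len(n_win) + j - 1L]]
      sc <- sc + ifelse(is.na(col), -Inf, col)
    }
    unname(sc)
  }

  rows <- purrr::imap(seqs, function(s, id) {
    if (nchar(s) < w) {
      warn(paste0("sequence ", id, " shorter than the PWM; skipped"))
      return(NULL)
    }
    fwd <- score_one(s)
    rev <- score_one(reverse_complement(s))
    L <- nchar(s)
    out <- list()
    hit_f <- which(fwd >= thr)
    if (base::length(hit_f)) {
      out$f <- tibble(seq_id = id, offset = hit_f - 1L, strand = "+",
                      score = fwd[hit_f])
    }
    hit_r <- which(rev >= thr)
    if (base::length(hit_r)) {
      # offset on the forward strand of the left end of the matched window
      out$r <- tibble(seq_id = id, offset = L - w - (hit_r - 1L), strand = "-",
                      score = rev[hit_r])
    }
    dplyr::bind_rows(out)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(seq_id = character(), offset = integer(),
                  strand = character(), score = numeric()))
  }
  out
}

#' Read and write promoter FASTA files
#'
#' Thin wrappers over Biostrings FASTA I/O returning/accepting named
#' character vectors.
#'
#' @param path FASTA file path.
#' @return `read_promoters()`: a named character vector.
#' @export
read_promoters <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @param promoters Named character vector of sequences.
#' @rdname read_promoters
#' @export
write_promoters <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("Inverted repeat %s (arm %d bp, spacer %d bp), %d/%d foreground vs %d/%d background promoters, p = %.3g\n",
              x$consensus, x$arm_len, x$spacer_len, x$k_fg, x$n_fg, x$k_bg,
              x$n_bg, x$p_value))
  invisible(x)
}

#' @export
print.motif_set <- function(x, ...) {
  cat("Ranked inverted-repeat motifs:", base::length(x), "\n")
  for (m in utils::head(x, 5)) print(m)
  invisible(x)
}
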