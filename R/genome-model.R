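# Restriction-fragment data model and readers/writers.
#
# All coordinates are 0-based, half-open ([start, end)), BED-native.
# Fragments tile each chromosome without gaps or overlaps and carry a
# genome-wide ordinal `frag_id` (increasing in genome order).

#' In silico restriction digest
#'
#' Cuts one or more chromosome sequences at every occurrence of a restriction
#' recognition site and returns the resulting fragment map. The default models
#' HindIII (A^AGCTT: recognition sequence `AAGCTT`, cleavage after the first
#' base). Matching is case-insensitive; ambiguous bases (`N`) never match the
#' recognition site, so masked stretches are left uncut. Overlapping site
#' matches are resolved left-to-right greedily.
#'
#' @param sequences Named character vector of chromosome sequences (names are
#'   chromosome labels; unnamed input is labelled `chr1`, `chr2`, ...).
#' @param site Recognition sequence (non-empty, A/C/G/T).
#' @param cut_offset Cut position within the site, in `[0, nchar(site)]`.
#'   The enzyme cleaves `cut_offset` bases after the match start.
#' @return A tibble with columns `frag_id`, `chrom`, `start`, `end`
#'   (0-based half-open). Fragments tile each chromosome exactly.
#' @examples
#' digest_sequence(c(chrA = "GGAAGCTTCC"))
#' @export
digest_sequence <- function(sequences, site = "AAGCTT", cut_offset = 1L) {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("chr", seq_along(sequences))
  }
  if (!is.character(site) || length(site) != 1 || !nzchar(site)) {
    stop("`site` must be a non-empty recognition sequence")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(site)) {
    stop("`cut_offset` must lie in [0, nchar(site)]")
  }
  site <- toupper(site)
  frags <- purrr::imap(sequences, function(seq, chrom) {
    if (!nzchar(seq)) stop("empty sequence for chromosome ", chrom)
    seq <- toupper(seq)
    if (grepl("[^ACGTN]", seq)) {
      stop("sequence for ", chrom, " contains characters outside {A,C,G,T,N}")
    }
    len <- nchar(seq)
    m <- Biostrings::matchPattern(site, Biostrings::DNAString(seq), fixed = TRUE)
    starts0 <- IRanges::start(m) - 1L # 0-based match starts, ascending
    # greedy left-to-right: skip matches overlapping an accepted one
    cuts <- integer(0)
    last_end <- -1L
    for (s in starts0) {
      if (s >= last_end) {
        cuts <- c(cuts, s + cut_offset)
        last_end <- s + nchar(site)
      }
    }
    bounds <- unique(c(0L, cuts[cuts > 0L & cuts < len], len))
    tibble::tibble(
      chrom = chrom,
      start = bounds[-length(bounds)],
      end   = bounds[-1]
    )
  })
  out <- dplyr::bind_rows(frags)
  out$frag_id <- seq_len(nrow(out))
  dplyr::select(out, "frag_id", "chrom", "start", "end")
}

#' Locate the fragment containing a position
#'
#' Maps genomic positions to the unique restriction fragment satisfying
#' `start <= pos < end` (half-open convention: a position equal to a fragment
#' end belongs to the next fragment).
#'
#' @param fragments Fragment map tibble (`frag_id`, `chrom`, `start`, `end`).
#' @param chrom Chromosome label(s); length 1 or `length(pos)`.
#' @param pos 0-based position(s).
#' @return Integer vector of `frag_id`s.
#' @export
locate_fragment <- function(fragments, chrom, pos) {
  stopifnot(length(chrom) == 1 || length(chrom) == length(pos))
  chrom <- rep_len(as.character(chrom), length(pos))
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    fr <- fragments[fragments$chrom == ch, ]
    if (nrow(fr) == 0) stop("unknown chromosome: ", ch)
    fr <- fr[order(fr$start), ]
    idx <- which(chrom == ch)
    p <- pos[idx]
    bad <- p < fr$start[1] | p >= fr$end[nrow(fr)]
    if (any(bad)) {
      stop("position ", p[which(bad)[1]], " outside tiled range on ", ch)
    }
    out[idx] <- fr$frag_id[findInterval(p, fr$start)]
  }
  out
}

#' Midpoints of restriction fragments
#'
#' `floor((start + end) / 2)` for each fragment.
#'
#' @param fragments Fragment map tibble.
#' @return Numeric vector of midpoints, parallel to the rows.
#' @export
fragment_midpoint <- function(fragments) {
  floor((fragments$start + fragments$end) / 2)
}

# Assert the fragment-tiling invariant; stops on gaps/overlaps.
validate_fragment_map <- function(fragments) {
  req <- c("frag_id", "chrom", "start", "end")
  if (!all(req %in% names(fragments))) {
    stop("fragment map must have columns ", paste(req, collapse = ", "))
  }
  by_chrom <- split(fragments, fragments$chrom)
  for (fr in by_chrom) {
    fr <- fr[order(fr$start), ]
    if (any(fr$start >= fr$end)) stop("fragment with start >= end on ", fr$chrom[1])
    if (nrow(fr) > 1 && any(fr$start[-1] != fr$end[-nrow(fr)])) {
      stop("fragments do not tile chromosome ", fr$chrom[1], " (gap or overlap)")
    }
    if (any(diff(fr$frag_id) <= 0)) {
      stop("frag_id not increasing in genome order on ", fr$chrom[1])
    }
  }
  invisible(fragments)
}

#' Read / write BED intervals
#'
#' Minimal BED3+ reader. Columns beyond the first three are preserved under
#' the conventional names `name`, `score`, `strand`, then `extra7`, `extra8`,
#' ... Records with `start >= end` are rejected with a warning; lines that do
#' not parse raise an error naming the line number. Coordinates are 0-based
#' half-open, exactly as stored.
#'
#' @param path File path.
#' @return A tibble with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  }
  width <- max(nf)
  get_col <- function(i) {
    vapply(parts, function(p) if (length(p) >= i) p[[i]] else NA_character_, "")
  }
  chrom <- get_col(1)
  start <- suppressWarnings(as.numeric(get_col(2)))
  end <- suppressWarnings(as.numeric(get_col(3)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("malformed BED line ", which(bad)[1], ": non-numeric coordinates")
  }
  out <- tibble::tibble(chrom = chrom, start = start, end = end)
  extra_names <- c("name", "score", "strand")
  if (width > 3) {
    for (i in 4:width) {
      nm <- if (i <= 6) extra_names[i - 3] else paste0("extra", i)
      out[[nm]] <- get_col(i)
    }
  }
  degenerate <- out$start >= out$end
  if (any(degenerate)) {
    warning(sum(degenerate), " BED record(s) with start >= end rejected")
    out <- out[!degenerate, ]
  }
  out
}

#' @param x Tibble with `chrom`, `start`, `end` and optional extra columns.
#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  x <- dplyr::relocate(x, "chrom", "start", "end")
  readr::write_tsv(x, path, col_names = FALSE)
  invisible(path)
}

#' Read / write a restriction-fragment map
#'
#' Tab-separated with header `chrom`, `start`, `end`, `frag_id`. The tiling
#' invariant (fragments cover each chromosome contiguously, `frag_id`
#' increasing in genome order) is enforced on load.
#'
#' @param path File path.
#' @return Fragment map tibble.
#' @export
read_fragment_map <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    start = readr::col_double(),
    end = readr::col_double(),
    frag_id = readr::col_integer()
  ))
  x <- dplyr::select(x, "frag_id", "chrom", "start", "end")
  validate_fragment_map(x)
  x
}

#' @param fragments Fragment map tibble.
#' @rdname read_fragment_map
#' @export
write_fragment_map <- function(fragments, path) {
  readr::write_tsv(
    dplyr::select(fragments, "chrom", "start", "end", "frag_id"), path
  )
  invisible(path)
}

#' Read a scored-interaction table
#'
#' Tab-separated dialect with header `bait_frag`, `prey_frag`, `cell_line`,
#' `capture`, `chicago_score`, `mppc`. The `mppc` field may be empty (absent
#' Peaky score). Fragment ids must resolve against the supplied fragment map;
#' interaction distance and the intrachromosomal flag are computed on load.
#' Duplicate (bait, prey, cell line, capture) rows and negative scores are
#' errors.
#'
#' @param path File path.
#' @param fragments Fragment map tibble used to resolve ids and distances.
#' @return Interaction tibble with derived `distance` (bp between fragment
#'   midpoints; `NA` for interchromosomal pairs) and `intrachromosomal`.
#' @export
read_interaction_table <- function(path, fragments) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    bait_frag = readr::col_integer(),
    prey_frag = readr::col_integer(),
    cell_line = readr::col_character(),
    capture = readr::col_character(),
    chicago_score = readr::col_double(),
    mppc = readr::col_double()
  ))
  unknown <- setdiff(unique(c(x$bait_frag, x$prey_frag)), fragments$frag_id)
  if (length(unknown) > 0) {
    stop("unknown fragment id(s) in interaction table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (any(x$chicago_score < 0, na.rm = TRUE)) {
    stop("negative chicago_score in interaction table")
  }
  if (any(x$mppc < 0 | x$mppc > 1, na.rm = TRUE)) {
    stop("mppc outside [0, 1] in interaction table")
  }
  if (any(x$bait_frag == x$prey_frag)) {
    stop("self-interaction (bait_frag == prey_frag) in interaction table")
  }
  key <- paste(x$bait_frag, x$prey_frag, x$cell_line, x$capture)
  if (anyDuplicated(key)) {
    stop("duplicate (bait, prey, cell_line, capture) rows: ambiguous score")
  }
  add_interaction_distance(x, fragments)
}

#' @param interactions Interaction tibble (core columns only are written).
#' @rdname read_interaction_table
#' @export
write_interaction_table <- function(interactions, path) {
  core <- c("bait_frag", "prey_frag", "cell_line", "capture",
            "chicago_score", "mppc")
  readr::write_tsv(dplyr::select(interactions, dplyr::all_of(core)), path)
  invisible(path)
}

#' Distance between two fragments of an interaction
#'
#' Absolute difference of fragment midpoints (`floor((start + end) / 2)`).
#' Both fragments must be on the same chromosome; callers should check the
#' `intrachromosomal` flag first.
#'
#' @param fragments Fragment map tibble.
#' @param bait_frag,prey_frag Fragment id vectors (recycled to equal length).
#' @return Numeric vector of distances in bp.
#' @export
interaction_distance <- function(fragments, bait_frag, prey_frag) {
  idx <- match(fragments$frag_id, fragments$frag_id) # identity; keep order
  mid <- fragment_midpoint(fragments)
  names(mid) <- fragments$frag_id
  ch <- fragments$chrom
  names(ch) <- fragments$frag_id
  b <- as.character(bait_frag)
  p <- as.character(prey_frag)
  if (anyNA(mid[b]) || anyNA(mid[p])) stop("unknown fragment id")
  if (any(ch[b] != ch[p])) {
    stop("interaction_distance() requires fragments on the same chromosome")
  }
  unname(abs(mid[b] - mid[p]))
}

#' Attach distance and intrachromosomal flag to interactions
#'
#' @param interactions Tibble with `bait_frag` and `prey_frag`.
#' @param fragments Fragment map tibble.
#' @return The input with `distance` (NA for interchromosomal pairs) and
#'   `intrachromosomal` columns replaced/added.
#' @export
add_interaction_distance <- function(interactions, fragments) {
  mid <- fragment_midpoint(fragments)
  bi <- match(interactions$bait_frag, fragments$frag_id)
  pi <- match(interactions$prey_frag, fragments$frag_id)
  if (anyNA(bi) || anyNA(pi)) stop("unknown fragment id in interactions")
  intra <- fragments$chrom[bi] == fragments$chrom[pi]
  d <- abs(mid[bi] - mid[pi])
  d[!intra] <- NA_real_
  interactions$intrachromosomal <- intra
  interactions$distance <- d
  interactions
}

#' Read a variant (CCV) table
#'
#' Tab-separated with header `variant_id`, `chrom`, `pos`, `risk_allele`,
#' `protective_allele`, `signal_id`; positions are 0-based. When a fragment
#' map is supplied, each variant is located on it and a `frag` column added.
#'
#' @param path File path.
#' @param fragments Optional fragment map for locating variants.
#' @return Variant tibble.
#' @export
read_variant_table <- function(path, fragments = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    variant_id = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_double(),
    risk_allele = readr::col_character(),
    protective_allele = readr::col_character(),
    signal_id = readr::col_character()
  ))
  if (any(x$risk_allele == x$protective_allele)) {
    stop("variant with identical risk and protective alleles")
  }
  if (!is.null(fragments)) {
    x$frag <- locate_fragment(fragments, x$chrom, x$pos)
  }
  x
}

#' Read a gene/TSS table
#'
#' Tab-separated with header `gene_id`, `name`, `biotype`, `strand`, `chrom`,
#' `tss` (one row per transcription start site; 0-based). Biotype must be
#' `coding` or `noncoding`.
#'
#' @param path File path.
#' @param fragments Optional fragment map; adds a `promoter_frag` column
#'   (fragment containing the TSS).
#' @return Gene tibble.
#' @export
read_gene_table <- function(path, fragments = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    name = readr::col_character(),
    biotype = readr::col_character(),
    strand = readr::col_character(),
    chrom = readr::col_character(),
    tss = readr::col_double()
  ))
  if (!all(x$biotype %in% c("coding", "noncoding"))) {
    stop("gene biotype must be 'coding' or 'noncoding'")
  }
  if (!all(x$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (!is.null(fragments)) {
    x$promoter_frag <- locate_fragment(fragments, x$chrom, x$tss)
  }
  x
}

#' Read an eQTL table
#'
#' Tab-separated with header `chrom`, `pos`, `egene_id`, `fdr` (eSNP position
#' 0-based). With `filter = TRUE` (default) only records with
#' `fdr < fdr_max` are retained (strict inequality).
#'
#' @param path File path.
#' @param fdr_max FDR threshold (default 0.05).
#' @param filter Apply the FDR filter on load?
#' @return eQTL tibble.
#' @export
read_eqtl_table <- function(path, fdr_max = 0.05, filter = TRUE) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_double(),
    egene_id = readr::col_character(),
    fdr = readr::col_double()
  ))
  if (any(is.na(x$fdr)) || any(x$fdr < 0 | x$fdr > 1)) {
    stop("eQTL fdr must be present and in [0, 1]")
  }
  if (filter) x <- x[x$fdr < fdr_max, ]
  x
}

#' Read a TAD interval set
#'
#' BED3 intervals; overlapping TADs within the set are rejected on load.
#'
#' @param path File path.
#' @return Tibble of `chrom`, `start`, `end`.
#' @export
read_tad_table <- function(path) {
  x <- read_bed(path)[, c("chrom", "start", "end")]
  for (tt in split(x, x$chrom)) {
    tt <- tt[order(tt$start), ]
    if (nrow(tt) > 1 && any(tt$start[-1] < tt$end[-nrow(tt)])) {
      stop("overlapping TAD intervals on ", tt$chrom[1])
    }
  }
  x
}
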