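#' Heaviside step function
#'
#' Indicator used throughout the graph pyramid: `H(x) = 1` when `x >= 0`
#' and `0` otherwise. The closed boundary (`H(0) = 1`) is what makes an edge
#' survive a threshold exactly equal to its weight.
#'
#' @param x Numeric vector; every element must be finite.
#' @return Numeric vector of 0s and 1s.
#' @examples
#' heaviside(c(-1, 0, 2.5))
#' @export
heaviside <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("`x` must be a finite numeric vector.", class = "ppsnet_input_error")
  }
  as.numeric(x >= 0)
}

#' Fuse an E-value and a bit-score into an EB-score
#'
#' E-values and bit-scores carry overlapping but distinct information about a
#' pairwise match: the bit-score measures alignment quality on a
#' search-space-free scale, the E-value the number of chance hits expected at
#' that score. The EB-score fuses them as
#' \deqn{eb = -\log(E)\cdot \mathrm{bitscore}, \qquad EB = eb\cdot H(eb),}
#' so marginal hits (E-value >= 1) collapse to 0 while confident hits grow with
#' both significance and score. The result is always nonnegative and is used
#' directly as an edge weight in the similarity network.
#'
#' @param evalue Nonnegative numeric vector of expectation values. Exact zeros
#'   (aligner underflow) are clamped to `evalue_floor` before the logarithm.
#' @param bitscore Numeric vector of bit-scores, recycled against `evalue`.
#' @param evalue_floor Positive clamp applied to underflowed E-values
#'   (default `1e-180`), keeping the score finite and order-preserving.
#' @param log_base Base of the logarithm (default natural log, the convention
#'   of E-value statistics).
#' @return Numeric vector of nonnegative EB-scores.
#' @examples
#' eb_score(1e-10, 100) # -ln(1e-10) * 100
#' eb_score(10, 50)     # insignificant hit -> 0
#' @export
eb_score <- function(evalue, bitscore, evalue_floor = 1e-180, log_base = exp(1)) {
  if (!is.numeric(evalue) || any(is.na(evalue)) || any(evalue < 0)) {
    abort("`evalue` must be numeric and >= 0.", class = "ppsnet_input_error")
  }
  if (!is.numeric(bitscore) || any(!is.finite(bitscore))) {
    abort("`bitscore` must be finite numeric.", class = "ppsnet_input_error")
  }
  eb <- -log(pmax(evalue, evalue_floor), base = log_base) * bitscore
  eb * heaviside(eb)
}

#' Read pairwise hits in 12-column tabular format
#'
#' Parses the standard 12-column tab-separated alignment report
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`). Only the identifiers, E-value and bit-score columns are
#' retained; `#`-prefixed comment lines are skipped. Malformed lines are
#' reported with their line numbers.
#'
#' @param path Path to a tabular hits file, or a character vector of lines.
#' @return A tibble with columns `query_id`, `subject_id`, `evalue`,
#'   `bitscore`, one row per hit (multiple HSPs for a pair are preserved;
#'   deduplication happens in [similarity_table()]).
#' @seealso [read_pair_scores()] for the generic 4-column score format.
#' @export
read_blast_tabular <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble(
      query_id = character(), subject_id = character(),
      evalue = numeric(), bitscore = numeric()
    ))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- idx[nf < 12L]
    abort(
      sprintf(
        "Tabular format error: line(s) %s have fewer than 12 tab-separated columns.",
        paste(head(bad, 5L), collapse = ", ")
      ),
      class = "ppsnet_format_error"
    )
  }
  qid <- vapply(fields, `[[`, character(1), 1L)
  sid <- vapply(fields, `[[`, character(1), 2L)
  ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 11L)))
  bs <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 12L)))
  bad <- is.na(ev) | is.na(bs) | ev < 0 | !nzchar(qid) | !nzchar(sid)
  if (any(bad)) {
    abort(
      sprintf(
        "Tabular format error: unparsable E-value/bit-score or empty id at line(s) %s.",
        paste(head(idx[bad], 5L), collapse = ", ")
      ),
      class = "ppsnet_format_error"
    )
  }
  tibble(query_id = qid, subject_id = sid, evalue = ev, bitscore = bs)
}

#' Read a generic pair-score table
#'
#' Reads a headered TSV with columns `id_a id_b evalue bitscore`, the
#' aligner-agnostic input format.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `query_id`, `subject_id`, `evalue`,
#'   `bitscore` (ready for [similarity_table()]).
#' @export
read_pair_scores <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'.", path), class = "ppsnet_format_error")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id_a", "id_b", "evalue", "bitscore")
  if (!all(need %in% names(df))) {
    abort(
      sprintf(
        "Pair-score table must have columns %s; found %s.",
        paste(need, collapse = ", "), paste(names(df), collapse = ", ")
      ),
      class = "ppsnet_format_error"
    )
  }
  if (!is.numeric(df$evalue) || !is.numeric(df$bitscore) || any(is.na(df$evalue)) ||
    any(is.na(df$bitscore)) || any(df$evalue < 0)) {
    abort("`evalue`/`bitscore` columns must be numeric with evalue >= 0.",
      class = "ppsnet_format_error"
    )
  }
  tibble(
    query_id = as.character(df$id_a), subject_id = as.character(df$id_b),
    evalue = df$evalue, bitscore = df$bitscore
  )
}

#' Symmetrize hits into a similarity table
#'
#' Collapses a hit list into one nonnegative EB-score per unordered sequence
#' pair. Reciprocal searches and multiple HSPs rarely agree exactly, but the
#' similarity network needs a single undirected weight, so the maximum
#' EB-score over all hits in either direction is kept (the strongest evidence
#' wins). Self-hits are dropped, as are pairs whose best EB-score is 0: a
#' zero-weight pair and an absent pair are indistinguishable downstream.
#'
#' @param hits A data frame of hits with columns `query_id`, `subject_id`,
#'   `evalue`, `bitscore` (as returned by [read_blast_tabular()],
#'   [read_pair_scores()] or [align_all()]).
#' @inheritParams eb_score
#' @return A tibble of class `pps_similarity` with columns `id_a`, `id_b`
#'   (lexicographically ordered within each row) and `eb`. Missing pairs mean
#'   EB = 0.
#' @examples
#' hits <- tibble::tibble(
#'   query_id = c("a", "b"), subject_id = c("b", "a"),
#'   evalue = c(1e-5, 1e-8), bitscore = c(40, 60)
#' )
#' similarity_table(hits)
#' @export
similarity_table <- function(hits, evalue_floor = 1e-180, log_base = exp(1)) {
  stopifnot(is.data.frame(hits))
  need <- c("query_id", "subject_id", "evalue", "bitscore")
  if (!all(need %in% names(hits))) {
    abort(sprintf("`hits` must have columns %s.", paste(need, collapse = ", ")),
      class = "ppsnet_input_error"
    )
  }
  hits <- filter(hits, .data$query_id != .data$subject_id)
  if (nrow(hits) == 0L) {
    return(new_similarity_table(tibble(
      id_a = character(), id_b = character(), eb = numeric()
    )))
  }
  out <- hits %>%
    mutate(
      eb = eb_score(.data$evalue, .data$bitscore,
        evalue_floor = evalue_floor, log_base = log_base
      ),
      id_a = pmin(.data$query_id, .data$subject_id),
      id_b = pmax(.data$query_id, .data$subject_id)
    ) %>%
    group_by(.data$id_a, .data$id_b) %>%
    summarise(eb = max(.data$eb), .groups = "drop") %>%
    filter(.data$eb > 0) %>%
    arrange(.data$id_a, .data$id_b)
  new_similarity_table(out)
}

new_similarity_table <- function(df) {
  structure(
    tibble::as_tibble(df[c("id_a", "id_b", "eb")]),
    class = c("pps_similarity", class(tibble::tibble()))
  )
}

#' Look up EB-scores for unordered pairs
#'
#' @param table A `pps_similarity` table.
#' @param a,b Character vectors of ids (recycled to common length).
#' @return Numeric vector of EB-scores; missing pairs and self-pairs yield 0.
#' @export
sim_lookup <- function(table, a, b) {
  stopifnot(inherits(table, "pps_similarity") || is.data.frame(table))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab_key <- paste(table$id_a, table$id_b, sep = "\r")
  eb <- table$eb[match(key, tab_key)]
  eb[is.na(eb) | a == b] <- 0
  eb
}

# ---- built-in local aligner -------------------------------------------------

#' Alignment parameters for the built-in local aligner
#'
#' Bundles the scoring system of the affine-gap Smith-Waterman aligner and the
#' Karlin-Altschul statistics used to convert a raw score into a bit-score
#' and E-value. Defaults are the standard gapped protein-search values
#' (BLOSUM62, gap open 11 / extend 1, lambda 0.267, kappa 0.041), so scores
#' are on a familiar magnitude scale.
#'
#' A gap of length k costs `gap_open + k * gap_extend`.
#'
#' @param substitution_matrix Either the name of a matrix shipped with
#'   Biostrings (e.g. `"BLOSUM62"`) or a square numeric matrix with amino-acid
#'   dimnames.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param lambda,kappa Positive Karlin-Altschul parameters: bitscore =
#'   `(lambda * S - log(kappa)) / log(2)`.
#' @param search_space Positive effective search space; `NULL` (default) uses
#'   the product of the two sequence lengths per pair, so
#'   `evalue = m * n * 2^(-bitscore)`.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1,
                             lambda = 0.267, kappa = 0.041,
                             search_space = NULL) {
  if (is.character(substitution_matrix)) {
    nm <- substitution_matrix
    env <- new.env()
    utils::data(list = nm, package = "Biostrings", envir = env)
    substitution_matrix <- get(nm, envir = env)
  }
  stopifnot(
    is.matrix(substitution_matrix),
    gap_open > 0, gap_extend > 0, lambda > 0, kappa > 0,
    is.null(search_space) || search_space > 0
  )
  structure(
    list(
      substitution_matrix = substitution_matrix, gap_open = gap_open,
      gap_extend = gap_extend, lambda = lambda, kappa = kappa,
      search_space = search_space
    ),
    class = "alignment_params"
  )
}

aa_alphabet <- function() c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

check_protein <- function(seq, arg) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) == 0L) {
    abort(sprintf("`%s` must be a nonempty protein sequence.", arg),
      class = "ppsnet_input_error"
    )
  }
  bad <- setdiff(unique(chars), aa_alphabet())
  if (length(bad)) {
    abort(
      sprintf("`%s` contains invalid residue(s): %s.", arg, paste(bad, collapse = ", ")),
      class = "ppsnet_input_error"
    )
  }
  chars
}

# Affine-gap Smith-Waterman, gap of length k costing open + k * extend.
# Plain-R DP; fine for the short synthetic sequences this package generates.
sw_score <- function(chars_a, chars_b, mat, gap_open, gap_extend) {
  m <- length(chars_a)
  n <- length(chars_b)
  ia <- match(chars_a, rownames(mat))
  ib <- match(chars_b, colnames(mat))
  go <- gap_open + gap_extend # cost of opening a length-1 gap
  ge <- gap_extend
  H_prev <- numeric(n + 1L)
  E_prev <- rep(-Inf, n + 1L)
  best <- 0
  for (i in seq_len(m)) {
    H_cur <- numeric(n + 1L)
    E_cur <- rep(-Inf, n + 1L)
    f <- -Inf # gap in sequence b, along current row
    srow <- mat[ia[i], ]
    for (j in seq_len(n)) {
      E_cur[j + 1L] <- max(E_prev[j + 1L] - ge, H_prev[j + 1L] - go)
      f <- max(f - ge, H_cur[j] - go)
      h <- max(0, H_prev[j] + srow[ib[j]], E_cur[j + 1L], f)
      H_cur[j + 1L] <- h
      if (h > best) best <- h
    }
    H_prev <- H_cur
    E_prev <- E_cur
  }
  best
}

#' Align one pair of protein sequences
#'
#' Computes the optimal local alignment score of two protein sequences under
#' an affine gap model, then converts the raw score S into a bit-score
#' `(lambda * S - ln kappa) / ln 2` and an E-value
#' `search_space * 2^(-bitscore)`. Deterministic; no heuristics (no word
#' seeding or X-drop), so it is an exact small-scale stand-in for a database
#' search tool.
#'
#' @param seq_a,seq_b Nonempty protein sequences over the 20 amino acids
#'   (plus `X`), as single strings.
#' @param params An [alignment_params()] object.
#' @param query_id,subject_id Identifiers stored in the returned hit.
#' @return A one-row tibble with columns `query_id`, `subject_id`, `evalue`,
#'   `bitscore` and `score` (the raw alignment score).
#' @export
align_pair <- function(seq_a, seq_b, params = alignment_params(),
                       query_id = "seq_a", subject_id = "seq_b") {
  stopifnot(inherits(params, "alignment_params"))
  ca <- check_protein(seq_a, "seq_a")
  cb <- check_protein(seq_b, "seq_b")
  s <- sw_score(
    ca, cb, params$substitution_matrix,
    params$gap_open, params$gap_extend
  )
  bits <- (params$lambda * s - log(params$kappa)) / log(2)
  space <- params$search_space %||% (length(ca) * length(cb))
  tibble(
    query_id = query_id, subject_id = subject_id,
    evalue = space * 2^(-bits), bitscore = bits, score = s
  )
}

#' Align all sequence pairs
#'
#' Runs [align_pair()] over every unordered pair of the given sequences,
#' producing a hit table ready for [similarity_table()].
#'
#' @param sequences Named character vector of protein sequences, or a data
#'   frame with columns `id` and `sequence`.
#' @param params An [alignment_params()] object.
#' @param self Include self-alignments? Default `FALSE` (they are dropped by
#'   [similarity_table()] anyway).
#' @return A tibble of hits (`query_id`, `subject_id`, `evalue`, `bitscore`,
#'   `score`).
#' @export
align_all <- function(sequences, params = alignment_params(), self = FALSE) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$id)
  }
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) {
    abort("`sequences` must be uniquely named.", class = "ppsnet_input_error")
  }
  pairs <- combn(ids, 2L)
  hits <- purrr::map2_dfr(
    pairs[1L, ], pairs[2L, ],
    function(a, b) {
      align_pair(sequences[[a]], sequences[[b]], params,
        query_id = a, subject_id = b
      )
    }
  )
  if (self) {
    selfs <- purrr::map_dfr(ids, function(a) {
      align_pair(sequences[[a]], sequences[[a]], params,
        query_id = a, subject_id = a
      )
    })
    hits <- bind_rows(hits, selfs)
  }
  hits
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a (multi-record, optionally wrapped) FASTA file.
#' @return A tibble with columns `id` (first word of the header) and
#'   `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  tibble(
    id = vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L),
    sequence = unname(as.character(x))
  )
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Data frame with columns `id` and `sequence`, or a named
#'   character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$id)
  }
  x <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
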