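#' Built-in sequence matcher for fixed-length tags
#'
#' A deliberately simple search used by the in-silico verification, homolog
#' retrieval, and the synthetic end-to-end tests; real-data users supply
#' externally computed 12-column tabular hits instead ([read_hits()]). Two
#' modes are available:
#'
#' * `"exact"` — every exact, full-length occurrence of a query (forward or
#'   reverse-complement) inside each subject sequence.
#' * `"global"` — ungapped end-to-end comparison of a query against
#'   equal-length subjects (both strands), keeping pairs whose identity is at
#'   least `min_identity`. This is the mode suited to homolog retrieval among
#'   fixed-length reduced-representation tags.
#'
#' E-values use a Karlin--Altschul-style approximation,
#' `E = m * n * 2^-bits` with `m` the total subject length and `n` the query
#' length, and `bits = 2 * matches - 3 * mismatches` (an exact hit of length
#' L scores `2 L` bits). The approximation exists solely so that E-value
#' cutoffs are exercisable with the built-in matcher; it is not calibrated
#' against any external search tool.
#'
#' @param queries,subjects Named character vectors of DNA sequences.
#' @param mode `"exact"` or `"global"`.
#' @param min_identity Minimum percent identity retained in `"global"` mode.
#' @return Hit tibble in the same shape as [read_hits()] (normalized
#'   ascending subject coordinates plus `strand`), sorted by query then
#'   E-value.
#' @export
match_sequences <- function(queries, subjects, mode = c("exact", "global"),
                            min_identity = 70) {
  mode <- match.arg(mode)
  stopifnot(!is.null(names(queries)), !is.null(names(subjects)))
  m_total <- sum(nchar(subjects))
  rows <- switch(mode,
    exact = match_exact(queries, subjects, m_total),
    global = match_global(queries, subjects, m_total, min_identity)
  )
  if (!nrow(rows)) return(empty_hits())
  rows %>% arrange(.data$query_id, .data$e_value, dplyr::desc(.data$bit_score))
}

empty_hits <- function() {
  tibble(query_id = character(), subject_id = character(),
         percent_identity = double(), alignment_length = double(),
         mismatches = double(), gap_opens = double(),
         q_start = double(), q_end = double(),
         s_start = double(), s_end = double(),
         e_value = double(), bit_score = double(), strand = character())
}

approx_evalue <- function(m_total, qlen, bits) {
  # floor the exponent so E stays a normal double even for long exact hits
  m_total * qlen * 2^(-pmin(bits, 1000))
}

match_exact <- function(queries, subjects, m_total) {
  out <- vector("list", length(queries) * length(subjects) * 2L)
  k <- 0L
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    qlen <- nchar(q)
    pats <- c(`+` = q, `-` = revcomp(q))
    for (strand in names(pats)) {
      locs <- stringr::str_locate_all(subjects, stringr::fixed(pats[[strand]]))
      for (si in seq_along(subjects)) {
        pos <- locs[[si]]
        if (nrow(pos) == 0) next
        bits <- 2 * qlen
        k <- k + 1L
        out[[k]] <- tibble(
          query_id = names(queries)[qi], subject_id = names(subjects)[si],
          percent_identity = 100, alignment_length = qlen,
          mismatches = 0, gap_opens = 0,
          q_start = 1, q_end = qlen,
          s_start = as.double(pos[, 1]), s_end = as.double(pos[, 2]),
          e_value = approx_evalue(m_total, qlen, bits), bit_score = bits,
          strand = strand
        )
      }
    }
  }
  bind_rows(out[seq_len(k)])
}

match_global <- function(queries, subjects, m_total, min_identity) {
  out <- list()
  for (qi in seq_along(queries)) {
    q <- toupper(queries[[qi]])
    qlen <- nchar(q)
    qv <- strsplit(q, "", fixed = TRUE)[[1]]
    qv_rc <- strsplit(revcomp(q), "", fixed = TRUE)[[1]]
    for (si in seq_along(subjects)) {
      s <- toupper(subjects[[si]])
      if (nchar(s) != qlen) next
      sv <- strsplit(s, "", fixed = TRUE)[[1]]
      for (strand in c("+", "-")) {
        qq <- if (strand == "+") qv else qv_rc
        matches <- sum(qq == sv)
        ident <- 100 * matches / qlen
        if (ident < min_identity) next
        bits <- 2 * matches - 3 * (qlen - matches)
        out[[length(out) + 1L]] <- tibble(
          query_id = names(queries)[qi], subject_id = names(subjects)[si],
          percent_identity = ident, alignment_length = qlen,
          mismatches = qlen - matches, gap_opens = 0,
          q_start = 1, q_end = as.double(qlen),
          s_start = 1, s_end = as.double(qlen),
          e_value = approx_evalue(m_total, qlen, bits),
          bit_score = as.double(bits), strand = strand
        )
      }
    }
  }
  bind_rows(out)
}
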