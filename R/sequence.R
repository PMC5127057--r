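# Sequence-side analyses: pairwise global alignment with percent identity,
# Schechter-Berger P-position labeling around the scissile bond, peptide
# fragment masses, and mass-based localization of the reactive-center-loop
# cleavage site.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Residue (monomer) masses in Da; peptide mass = sum + water.
MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MONO <- 18.010565
WATER_AVG <- 18.0153

#' Alignment scoring configuration
#'
#' Defaults are the classic pairwise protein settings: BLOSUM62
#' substitution scores with affine gap penalties (a gap of length L costs
#' `gap_open + gap_extend * L`), gap open 10, extend 0.5. Supplying
#' `match`/`mismatch` replaces the matrix by a uniform one (useful for
#' identity-style scoring).
#'
#' @param match,mismatch optional scalar scores replacing the substitution
#'   matrix.
#' @param matrix substitution matrix name (`"BLOSUM62"`) or a named numeric
#'   matrix over the amino-acid alphabet.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return a list used by [global_align()].
#' @export
align_scoring <- function(match = NULL, mismatch = NULL, matrix = "BLOSUM62",
                          gap_open = 10, gap_extend = 0.5) {
  if (!is.null(match) || !is.null(mismatch)) {
    stopifnot(!is.null(match), !is.null(mismatch))
    m <- base::matrix(mismatch, length(AA20), length(AA20),
                      dimnames = list(AA20, AA20))
    diag(m) <- match
  } else if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    m <- e[[matrix]]
  } else {
    m <- matrix
  }
  list(matrix = m, gap_open = gap_open, gap_extend = gap_extend)
}

#' Global pairwise alignment (Needleman-Wunsch with affine gaps)
#'
#' Gotoh three-state dynamic program with deterministic tie-breaking
#' (diagonal preferred over up over left) and end gaps penalized as
#' ordinary gaps. Identity is reported over all aligned columns by default
#' (columns with a gap count in the denominator); set
#' `denominator = "shorter"` to divide by the shorter sequence length
#' instead - published identity percentages rarely state their convention.
#'
#' @param a,b amino-acid sequences (strings or [serpin_record()]s).
#' @param scoring an [align_scoring()] configuration.
#' @param denominator `"aligned_columns"` or `"shorter"`.
#' @return an object of class `alignment_result`: `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `score`,
#'   `identity_pct`, `n_identical`, `n_aligned_columns`.
#' @examples
#' global_align("ACDE", "ACDF", align_scoring(match = 1, mismatch = 0))
#' @export
global_align <- function(a, b, scoring = align_scoring(),
                         denominator = c("aligned_columns", "shorter")) {
  denominator <- match.arg(denominator)
  if (inherits(a, "serpin_record")) a <- a$residues
  if (inherits(b, "serpin_record")) b <- b$residues
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop_input("sequences must be non-empty")
  bad <- c(validate_aa(a), validate_aa(b))
  if (length(bad))
    stop_input("invalid residues: %s", paste(unique(bad), collapse = ", "))
  # canonical orientation so that (a, b) and (b, a) give mirror-identical
  # alignments (tie-breaking is otherwise orientation-dependent)
  swapped <- a > b
  if (swapped) { tmp <- a; a <- b; b <- tmp }
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- scoring$matrix
  go <- scoring$gap_open; ge <- scoring$gap_extend
  gap1 <- go + ge  # first residue of a gap
  NEG <- -1e18

  M <- Ix <- Iy <- matrix(NEG, n + 1L, m + 1L)
  pM <- pIx <- pIy <- matrix(0L, n + 1L, m + 1L)
  M[1, 1] <- 0
  if (n > 0) Ix[2:(n + 1), 1] <- -(go + ge * seq_len(n))
  if (m > 0) Iy[1, 2:(m + 1)] <- -(go + ge * seq_len(m))
  pIx[, 1] <- 2L; pIy[1, ] <- 3L

  for (i in seq_len(n)) {
    Si <- S[A[i], ]
    for (j in seq_len(m)) {
      s <- Si[B[j]]
      cand <- c(M[i, j], Ix[i, j], Iy[i, j])
      w <- which.max(cand)  # ties: M > Ix > Iy (diagonal > up > left)
      M[i + 1, j + 1] <- cand[w] + s
      pM[i + 1, j + 1] <- w
      cx <- c(M[i, j + 1] - gap1, Ix[i, j + 1] - ge)
      wx <- which.max(cx)
      Ix[i + 1, j + 1] <- cx[wx]
      pIx[i + 1, j + 1] <- c(1L, 2L)[wx]
      cy <- c(M[i + 1, j] - gap1, Iy[i + 1, j] - ge)
      wy <- which.max(cy)
      Iy[i + 1, j + 1] <- cy[wy]
      pIy[i + 1, j + 1] <- c(1L, 3L)[wy]
    }
  }

  fin <- c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  state <- which.max(fin)
  score <- fin[state]

  # traceback
  i <- n; j <- m
  ga <- character(0); gb <- character(0)
  while (i > 0 || j > 0) {
    if (state == 1L) {
      prev <- pM[i + 1, j + 1]
      ga <- c(A[i], ga); gb <- c(B[j], gb)
      i <- i - 1L; j <- j - 1L
      state <- prev
    } else if (state == 2L) {
      prev <- pIx[i + 1, j + 1]
      ga <- c(A[i], ga); gb <- c("-", gb)
      i <- i - 1L
      state <- prev
    } else {
      prev <- pIy[i + 1, j + 1]
      ga <- c("-", ga); gb <- c(B[j], gb)
      j <- j - 1L
      state <- prev
    }
  }

  n_cols <- length(ga)
  n_ident <- sum(ga == gb & ga != "-")
  denom <- if (denominator == "aligned_columns") n_cols else min(n, m)
  if (swapped) { tmp <- ga; ga <- gb; gb <- tmp }
  structure(
    list(aligned_a = paste(ga, collapse = ""),
         aligned_b = paste(gb, collapse = ""),
         score = score, identity_pct = 100 * n_ident / denom,
         n_identical = n_ident, n_aligned_columns = n_cols),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result: score %.1f, identity %.1f%% (%d/%d columns)>\n",
              x$score, x$identity_pct, x$n_identical, x$n_aligned_columns))
  invisible(x)
}

#' Schechter-Berger P-position labels for a peptide bond
#'
#' Residue `j <= p1` is labeled `P(p1 - j + 1)` (counting N-terminally
#' from the scissile bond); residue `j > p1` is `P(j - p1)'`. The bond
#' between P1 and P1' is the scissile bond itself.
#'
#' @param bond length-2 vector `c(i, i + 1)` of consecutive residue
#'   indices.
#' @param p1_index 1-based index of the P1 residue.
#' @return character vector of two labels, e.g. `c("P3", "P2")`.
#' @examples
#' label_p_positions(c(338, 339), p1_index = 340)  # "P3" "P2"
#' @export
label_p_positions <- function(bond, p1_index) {
  bond <- as.integer(bond)
  if (length(bond) != 2L || bond[2] != bond[1] + 1L || any(bond < 1L))
    stop_input("bond must be consecutive positive indices (i, i+1)")
  p1_index <- as.integer(p1_index)
  stopifnot(p1_index >= 1L)
  lab <- function(j) {
    if (j <= p1_index) paste0("P", p1_index - j + 1L)
    else paste0("P", j - p1_index, "'")
  }
  c(lab(bond[1]), lab(bond[2]))
}

#' Peptide / fragment mass
#'
#' Sum of residue masses plus one water (18.010565 Da monoisotopic,
#' 18.0153 Da average). Cysteine is unmodified by default; pass
#' `cys_carbamidomethyl = TRUE` to add +57.02146 Da per Cys
#' (iodoacetamide alkylation).
#'
#' @param seq amino-acid string or [serpin_record()].
#' @param span optional 1-based inclusive `c(start, end)`; `NULL` uses the
#'   whole sequence. A degenerate empty span yields the water mass.
#' @param mass_type `"monoisotopic"` or `"average"`.
#' @param cys_carbamidomethyl add the carbamidomethyl fixed modification
#'   on Cys.
#' @return mass in Da.
#' @examples
#' fragment_mass("G")  # 75.032025
#' @export
fragment_mass <- function(seq, span = NULL,
                          mass_type = c("monoisotopic", "average"),
                          cys_carbamidomethyl = FALSE) {
  mass_type <- match.arg(mass_type)
  if (inherits(seq, "serpin_record")) seq <- seq$residues
  seq <- toupper(seq)
  bad <- validate_aa(seq)
  if (length(bad))
    stop_input("invalid residues: %s", paste(unique(bad), collapse = ", "))
  tab <- if (mass_type == "monoisotopic") MONO_MASS else AVG_MASS
  water <- if (mass_type == "monoisotopic") WATER_MONO else WATER_AVG
  n <- nchar(seq)
  if (is.null(span)) span <- c(1L, n)
  if (length(span) != 2L || span[1] < 1L || span[2] > n)
    stop_input("span out of range for a %d-residue sequence", n)
  if (span[2] < span[1]) return(water)  # empty fragment
  chars <- strsplit(substr(seq, span[1], span[2]), "")[[1]]
  mass <- sum(tab[chars]) + water
  if (cys_carbamidomethyl) mass <- mass + 57.02146 * sum(chars == "C")
  mass
}

#' Localize a cleavage site from an observed fragment mass
#'
#' Enumerates every peptide bond of the sequence (optionally restricted to
#' the annotated RCL span), computes the N- or C-terminal fragment mass
#' generated by cleavage at each bond, and returns the bonds whose
#' fragment matches the observed mass within `tolerance_ppm`, ranked by
#' absolute mass error. When the record carries a `p1_index`,
#' Schechter-Berger labels are attached to each assignment.
#'
#' @param record a [serpin_record()].
#' @param observed_mass observed fragment mass (Da), > water.
#' @param fragment_terminus `"N"` or `"C"`: which fragment the mass
#'   belongs to.
#' @param tolerance_ppm match tolerance in ppm (> 0).
#' @param restrict_to_rcl only consider bonds inside the record's
#'   `rcl_span`.
#' @param mass_type `"monoisotopic"` or `"average"`.
#' @return data.frame of class `cleavage_assignment` with columns
#'   `bond_i`, `bond_j`, `fragment_terminus`, `theoretical_mass`,
#'   `observed_mass`, `error_ppm`, `p_label_i`, `p_label_j`; zero rows
#'   when nothing matches (not an error).
#' @export
map_cleavage_site <- function(record, observed_mass,
                              fragment_terminus = c("N", "C"),
                              tolerance_ppm = 20, restrict_to_rcl = FALSE,
                              mass_type = c("monoisotopic", "average")) {
  fragment_terminus <- match.arg(fragment_terminus)
  mass_type <- match.arg(mass_type)
  stopifnot(inherits(record, "serpin_record"))
  water <- if (mass_type == "monoisotopic") WATER_MONO else WATER_AVG
  if (!is_scalar_number(observed_mass) || observed_mass <= water) {
    return(empty_assignment())
  }
  if (!is_scalar_number(tolerance_ppm) || tolerance_ppm <= 0)
    stop_input("tolerance_ppm must be > 0")
  n <- nchar(record$residues)
  bonds <- seq_len(n - 1L)
  if (restrict_to_rcl) {
    if (is.null(record$rcl_span))
      stop_input("'%s' has no rcl_span annotation", record$seq_id)
    bonds <- bonds[bonds >= record$rcl_span[1] & bonds < record$rcl_span[2]]
  }
  theo <- vapply(bonds, function(i) {
    span <- if (fragment_terminus == "N") c(1L, i) else c(i + 1L, n)
    fragment_mass(record$residues, span, mass_type)
  }, 0)
  err <- (observed_mass - theo) / theo * 1e6
  keep <- abs(err) <= tolerance_ppm
  if (!any(keep)) return(empty_assignment())
  out <- data.frame(
    bond_i = bonds[keep], bond_j = bonds[keep] + 1L,
    fragment_terminus = fragment_terminus,
    theoretical_mass = theo[keep], observed_mass = observed_mass,
    error_ppm = err[keep], p_label_i = NA_character_,
    p_label_j = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(record$p1_index)) {
    labs <- t(vapply(out$bond_i, function(i)
      label_p_positions(c(i, i + 1L), record$p1_index), character(2)))
    out$p_label_i <- labs[, 1]; out$p_label_j <- labs[, 2]
  }
  out <- out[order(abs(out$error_ppm)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cleavage_assignment", class(out))
  out
}

empty_assignment <- function() {
  out <- data.frame(bond_i = integer(0), bond_j = integer(0),
                    fragment_terminus = character(0),
                    theoretical_mass = numeric(0),
                    observed_mass = numeric(0), error_ppm = numeric(0),
                    p_label_i = character(0), p_label_j = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("cleavage_assignment", class(out))
  out
}

#' Project a reference RCL annotation onto a query sequence
#'
#' Aligns the query to a reference serpin whose reactive-center-loop span
#' (and optionally P1 index) is known, and maps the annotation through the
#' alignment columns onto query coordinates.
#'
#' @param query a [serpin_record()] (or sequence string) to annotate.
#' @param reference a `serpin_record` with `rcl_span` set.
#' @param scoring an [align_scoring()] configuration.
#' @return the query record with `rcl_span` (and `p1_index`, when the
#'   reference has one and it maps onto a query residue) filled in.
#' @export
annotate_rcl <- function(query, reference, scoring = align_scoring()) {
  if (!inherits(query, "serpin_record"))
    query <- serpin_record("query", query)
  stopifnot(inherits(reference, "serpin_record"))
  if (is.null(reference$rcl_span))
    stop_input("reference '%s' has no rcl_span", reference$seq_id)
  al <- global_align(reference$residues, query$residues, scoring)
  ra <- strsplit(al$aligned_a, "")[[1]]  # reference
  qa <- strsplit(al$aligned_b, "")[[1]]  # query
  rpos <- cumsum(ra != "-")
  qpos <- cumsum(qa != "-")
  map_ref_to_query <- function(rp) {
    cols <- which(rpos == rp & ra != "-")
    if (!length(cols) || qa[cols[1]] == "-") return(NA_integer_)
    qpos[cols[1]]
  }
  # span endpoints: nearest mapped query residues inside the span
  span_cols <- which(rpos >= reference$rcl_span[1] &
                     rpos <= reference$rcl_span[2] & qa != "-")
  if (!length(span_cols))
    stop_input("reference RCL aligns entirely to gaps in the query")
  q_span <- range(qpos[span_cols])
  p1 <- if (!is.null(reference$p1_index))
    map_ref_to_query(reference$p1_index) else NULL
  if (!is.null(p1) && is.na(p1)) p1 <- NULL
  serpin_record(query$seq_id, query$residues,
                signal_peptide_span = query$signal_peptide_span,
                rcl_span = as.integer(q_span), p1_index = p1,
                cleavage_bond = query$cleavage_bond)
}

#' Flag a serpin hinge region by small-residue content
#'
#' The hinge (the N-terminal part of the reactive-center loop of
#' inhibitory serpins) is enriched in small residues. This heuristic
#' reports the first run of at least `min_run` consecutive residues from
#' the set G/A/S/V, searched within `rcl_span` when the record has one.
#'
#' @param record a [serpin_record()] or sequence string.
#' @param min_run minimum run length (default 4).
#' @return integer `c(start, end)` of the run (1-based inclusive), or
#'   `NULL` when no qualifying run exists.
#' @export
find_hinge <- function(record, min_run = 4L) {
  if (inherits(record, "serpin_record")) {
    seq <- record$residues
    window <- record$rcl_span %||% c(1L, nchar(seq))
  } else {
    seq <- toupper(record)
    window <- c(1L, nchar(seq))
  }
  chars <- strsplit(seq, "")[[1]]
  small <- chars %in% c("G", "A", "S", "V")
  small[-(window[1]:window[2])] <- FALSE
  r <- rle(small)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_run)
  if (!length(hit)) return(NULL)
  c(starts[hit[1]], ends[hit[1]])
}
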