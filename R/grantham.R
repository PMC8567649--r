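# Grantham amino-acid distance: D(i,j) = rho * sqrt(alpha*(c_i-c_j)^2 +
# beta*(p_i-p_j)^2 + gamma*(v_i-v_j)^2), built from side-chain composition
# (c), polarity (p) and molecular volume (v) of the 20 canonical residues.

#' Canonical amino-acid residue order
#'
#' Fixed one-letter ordering used for all matrix import/export.
#' @return Character vector of the 20 canonical residues.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Physicochemical property table for the Grantham distance
#'
#' Side-chain atomic composition (`c`), polarity (`p`) and molecular volume
#' (`v`) for the 20 canonical amino acids. These are the classic property
#' values underlying the integer Grantham substitution matrix; they are
#' embedded as a versioned fixture so the matrix can be rebuilt from first
#' principles with no external files.
#'
#' @return A data.frame with columns `residue`, `c`, `p`, `v` (20 rows).
#' @export
grantham_properties <- function() {
  props <- data.frame(
    residue = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
                "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
    c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
          0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
    p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
          6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
    v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
          136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
    stringsAsFactors = FALSE
  )
  props[match(aa_alphabet(), props$residue), , drop = FALSE]
}

#' Weights and scale of the Grantham distance formula
#'
#' @param alpha Weight on the composition term.
#' @param beta Weight on the polarity term.
#' @param gamma Weight on the volume term.
#' @param rho Global scale factor. The default `NULL` calibrates rho so the
#'   mean of the 190 off-diagonal distances is exactly 100 (this calibrated
#'   value, 50.78988..., reproduces the published integer matrix including
#'   its extreme entries; the frequently quoted constant 50.723 can be
#'   supplied explicitly but rounds the Trp-Cys entry to 214 rather than
#'   the published 215).
#' @return A list with components `alpha`, `beta`, `gamma`, `rho`.
#' @export
grantham_params <- function(alpha = 1.833, beta = 0.1018, gamma = 0.000399,
                            rho = NULL) {
  stopifnot(alpha > 0, beta > 0, gamma > 0, is.null(rho) || rho > 0)
  list(alpha = alpha, beta = beta, gamma = gamma, rho = rho)
}

# Unscaled formula evaluation over all residue pairs.
.grantham_raw <- function(props, params) {
  needed <- setdiff(aa_alphabet(), props$residue)
  if (length(needed) > 0) {
    stop("property table is missing residue(s): ",
         paste(needed, collapse = ", "))
  }
  if (anyDuplicated(props$residue)) {
    stop("duplicate residues in property table")
  }
  if (!all(is.finite(props$c)) || !all(is.finite(props$p)) ||
      !all(is.finite(props$v))) {
    stop("non-finite property value in table")
  }
  ord <- match(aa_alphabet(), props$residue)
  cc <- props$c[ord]; pp <- props$p[ord]; vv <- props$v[ord]
  sqrt(params$alpha * outer(cc, cc, "-")^2 +
       params$beta  * outer(pp, pp, "-")^2 +
       params$gamma * outer(vv, vv, "-")^2)
}

#' Calibrate the Grantham scale factor
#'
#' Returns the rho for which the mean of the 190 off-diagonal distances
#' equals 100 under the given properties and weights.
#'
#' @inheritParams build_grantham_matrix
#' @return The calibrated scale factor (a single number).
#' @export
calibrate_rho <- function(props = grantham_properties(),
                          params = grantham_params()) {
  raw <- .grantham_raw(props, params)
  100 / mean(raw[upper.tri(raw)])
}

#' Build the Grantham amino-acid distance matrix
#'
#' Evaluates the distance formula on the property fixture for all 190
#' residue pairs. In `"published-integer"` mode (the default, matching the
#' classic integer matrix) entries are rounded half-up to integers;
#' `"continuous"` mode keeps full precision for sensitivity analysis.
#'
#' @param props Property table, see [grantham_properties()].
#' @param params Formula weights and scale, see [grantham_params()].
#' @param mode `"published-integer"` or `"continuous"`.
#' @return A 20x20 symmetric numeric matrix with zero diagonal, residues of
#'   [aa_alphabet()] as dimnames, and attributes `mode` and `rho`.
#' @examples
#' m <- build_grantham_matrix()
#' m["L", "I"]  # 5
#' m["W", "C"]  # 215, the largest entry
#' @export
build_grantham_matrix <- function(props = grantham_properties(),
                                  params = grantham_params(),
                                  mode = c("published-integer",
                                           "continuous")) {
  mode <- match.arg(mode)
  rho <- if (is.null(params$rho)) calibrate_rho(props, params) else params$rho
  m <- .grantham_raw(props, params) * rho
  if (mode == "published-integer") m <- floor(m + 0.5)  # round half-up
  dimnames(m) <- list(aa_alphabet(), aa_alphabet())
  attr(m, "mode") <- mode
  attr(m, "rho") <- rho
  m
}

#' Look up the Grantham distance between two residues
#'
#' @param a,b Single canonical one-letter residue codes.
#' @param m Matrix from [build_grantham_matrix()].
#' @return The distance `m[a, b]`.
#' @export
grantham_distance <- function(a, b, m = build_grantham_matrix()) {
  bad <- setdiff(c(a, b), aa_alphabet())
  if (length(bad) > 0) {
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  }
  m[a, b]
}

#' Write / read a Grantham matrix as labelled TSV
#'
#' The file is a 20x20 tab-separated table with residue row and column
#' labels in the canonical order of [aa_alphabet()]; a `#` header line
#' records the mode and scale.
#'
#' @param m Matrix from [build_grantham_matrix()].
#' @param path File path.
#' @return `write_grantham_tsv()` returns `path` invisibly;
#'   `read_grantham_tsv()` returns the matrix with its attributes restored.
#' @export
write_grantham_tsv <- function(m, path) {
  header <- sprintf("# grantham distance matrix; mode=%s; rho=%.10g; residues in fixed canonical order",
                    attr(m, "mode"), attr(m, "rho"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("residue", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], format(m[i, ], trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_grantham_tsv
#' @export
read_grantham_tsv <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")][1]
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           check.names = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$residue
  m <- m[aa_alphabet(), aa_alphabet()]
  if (!is.na(header)) {
    mode <- sub(".*mode=([^;]+);.*", "\\1", header)
    rho <- suppressWarnings(as.numeric(sub(".*rho=([^;]+);.*", "\\1", header)))
    attr(m, "mode") <- mode
    attr(m, "rho") <- rho
  }
  m
}
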