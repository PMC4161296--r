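# Fitness landscapes over sequence space. Broad/multi/multiplicative peaks are
# implicit (membership by Hamming distance to centers); rugged landscapes are
# tabulated over a fully enumerated small space (guard A^L <= 1e6).

ENUM_GUARD <- 1e6

#' Broad-peak landscape
#'
#' A target set consisting of every sequence within Hamming radius `w` of a
#' center sequence, embedded in an otherwise flat (fitness 1) landscape.
#' Target sequences carry relative fitness `advantage` (default 1: the purely
#' neutral discovery question).
#'
#' @param space A [seq_space()].
#' @param center Center sequence (character string of length `space$L`).
#' @param w Integer peak radius, `0 <= w <= L`. Alternatively give `c_frac`.
#' @param c_frac Peak width as a fraction of `L`; `w = floor(c_frac * L)`.
#' @param advantage Relative fitness of target sequences (> 0).
#' @return A landscape object (class `broad_peak`/`pw_landscape`).
#' @export
broad_peak <- function(space, center, w = NULL, c_frac = NULL, advantage = 1) {
  check_sequence(center, space)
  if (is.null(w)) {
    stopifnot(!is.null(c_frac), c_frac >= 0, c_frac <= 1)
    w <- floor(c_frac * space$L)
  }
  stopifnot(w >= 0, w <= space$L, advantage > 0)
  structure(list(space = space, centers = center, w = as.integer(w),
                 advantage = advantage),
            class = c("broad_peak", "pw_landscape"))
}

#' Multi-peak landscape
#'
#' The union of `m` broad peaks of shared radius `w`; fitness is flat outside.
#'
#' @inheritParams broad_peak
#' @param centers Character vector of `m >= 1` center sequences.
#' @export
multi_peak <- function(space, centers, w, advantage = 1) {
  stopifnot(length(centers) >= 1, w >= 0, w <= space$L, advantage > 0)
  for (s in centers) check_sequence(s, space)
  structure(list(space = space, centers = centers, w = as.integer(w),
                 advantage = advantage),
            class = c("multi_peak", "pw_landscape"))
}

#' Multiplicative-gradient landscape
#'
#' Fitness `(1 + sigma)^(L - d(s, center))`: every step toward the center
#' multiplies fitness by `1 + sigma`. With `sigma = 0` the landscape is flat.
#' A broad peak of radius `w` around the center is the embedded target set.
#'
#' @inheritParams broad_peak
#' @param sigma Per-step multiplicative advantage, `>= 0`.
#' @export
multiplicative_peak <- function(space, center, sigma, w) {
  check_sequence(center, space)
  stopifnot(sigma >= 0, w >= 0, w <= space$L)
  structure(list(space = space, centers = center, sigma = sigma,
                 w = as.integer(w)),
            class = c("multiplicative_peak", "pw_landscape"))
}

#' @export
print.pw_landscape <- function(x, ...) {
  cat("<", class(x)[1], "> L = ", x$space$L, ", A = ", x$space$A,
      ", m = ", length(x$centers), ", w = ", x$w,
      if (!is.null(x$sigma)) paste0(", sigma = ", x$sigma), "\n", sep = "")
  invisible(x)
}

#' Fitness of sequences under a landscape
#' @param land A landscape object.
#' @param s Character vector of sequences.
#' @return Numeric vector of fitness values.
#' @export
fitness_of <- function(land, s) UseMethod("fitness_of")

#' @export
fitness_of.broad_peak <- function(land, s) {
  ifelse(is_target(land, s), land$advantage, 1)
}

#' @export
fitness_of.multi_peak <- fitness_of.broad_peak

#' @export
fitness_of.multiplicative_peak <- function(land, s) {
  d <- hamming_distance(s, rep(land$centers, length(s)))
  (1 + land$sigma)^(land$space$L - d)
}

#' @export
fitness_of.tabulated_landscape <- function(land, s) {
  land$fitness[match(s, land$sequence)]
}

#' Target-set membership
#' @inheritParams fitness_of
#' @return Logical vector.
#' @export
is_target <- function(land, s) UseMethod("is_target")

#' @export
is_target.broad_peak <- function(land, s) {
  dmin <- rep(Inf, length(s))
  for (ctr in land$centers)
    dmin <- pmin(dmin, hamming_distance(s, rep(ctr, length(s))))
  dmin <= land$w
}

#' @export
is_target.multi_peak <- is_target.broad_peak

#' @export
is_target.multiplicative_peak <- is_target.broad_peak

#' @export
is_target.tabulated_landscape <- function(land, s) {
  tgt <- attr(land, "target")
  if (is.null(tgt)) stop("tabulated landscape has no target set; apply ",
                         "approximate_threshold() or approximate_plateau()")
  s %in% tgt
}

# ---- enumeration of small spaces ------------------------------------------

# integer codes 0..A^L-1; digit for position 1 is most significant
enum_check <- function(space) {
  if (space$A^space$L > ENUM_GUARD)
    stop("space too large to enumerate: A^L = ", space$A^space$L,
         " > ", ENUM_GUARD)
}

#' Enumerate every sequence of a small space
#'
#' @param space A [seq_space()] with `A^L <= 1e6`.
#' @return Character vector of all `A^L` sequences in lexicographic order.
#' @export
all_sequences <- function(space) {
  enum_check(space)
  n <- space$A^space$L
  code <- 0:(n - 1)
  chars <- matrix("", n, space$L)
  for (i in space$L:1) {
    chars[, i] <- space$alphabet[(code %% space$A) + 1]
    code <- code %/% space$A
  }
  apply(chars, 1, paste, collapse = "")
}

# row i = 1-based indices (into lexicographic enumeration) of the L*A
# "set position p to letter a" variants of sequence i; the A columns whose
# letter equals the current one are marked 0. Column order is position-major,
# alphabet ascending — the deterministic neighbor order.
neighbor_index <- function(space) {
  enum_check(space)
  n <- space$A^space$L
  code <- 0:(n - 1)
  idx <- matrix(0L, n, space$L * space$A)
  col <- 0L
  for (p in seq_len(space$L)) {
    place <- space$A^(space$L - p)
    digit <- (code %/% place) %% space$A
    for (a in 0:(space$A - 1)) {
      col <- col + 1L
      nc <- code + (a - digit) * place
      nc[a == digit] <- -1L          # self, not a neighbor
      idx[, col] <- nc + 1L
    }
  }
  idx
}

#' Tabulated landscape over a fully enumerated space
#'
#' @param space A [seq_space()] with `A^L <= 1e6`.
#' @param fitness Either a numeric vector aligned with [all_sequences()] or a
#'   named vector/function mapping each sequence to a non-negative fitness.
#' @return A tibble of class `tabulated_landscape` with columns `sequence`,
#'   `fitness` and the space in `attr(, "space")`.
#' @export
tabulated_landscape <- function(space, fitness) {
  seqs <- all_sequences(space)
  f <- if (is.function(fitness)) {
    vapply(seqs, fitness, numeric(1), USE.NAMES = FALSE)
  } else if (!is.null(names(fitness))) {
    unname(fitness[seqs])
  } else {
    stopifnot(length(fitness) == length(seqs))
    as.numeric(fitness)
  }
  if (anyNA(f)) stop("fitness must be defined for every sequence of the space")
  if (any(f < 0)) stop("fitness must be non-negative")
  out <- tibble::tibble(sequence = seqs, fitness = f)
  class(out) <- c("tabulated_landscape", class(out))
  attr(out, "space") <- space
  out
}

#' Rough-Mount-Fuji rugged landscape generator
#'
#' A linear slope toward an anchor sequence plus i.i.d. Gaussian roughness:
#' `f(s) = theta * (L - d(s, anchor)) + eps_s`, `eps_s ~ N(0, noise_sd^2)`,
#' shifted upward if needed so the minimum fitness is >= 0. With
#' `noise_sd = 0` the landscape is a smooth cone with its unique local maximum
#' at the anchor; with `theta = 0` it is a pure random field whose expected
#' fraction of strict local maxima is `1 / (L(A-1) + 1)`.
#'
#' @param space A [seq_space()] with `A^L <= 1e6`.
#' @param anchor Anchor (cone apex) sequence.
#' @param theta Slope per mutational step toward the anchor (>= 0).
#' @param noise_sd Standard deviation of the i.i.d. roughness term.
#' @return A [tabulated_landscape()]. Uses R's RNG; seed with [set.seed()].
#' @export
generate_rugged <- function(space, anchor, theta = 1, noise_sd = 1) {
  enum_check(space)
  check_sequence(anchor, space)
  stopifnot(theta >= 0, noise_sd >= 0)
  seqs <- all_sequences(space)
  d <- hamming_distance(seqs, rep(anchor, length(seqs)))
  f <- theta * (space$L - d) + stats::rnorm(length(seqs), 0, noise_sd)
  if (min(f) < 0) f <- f - min(f)
  tabulated_landscape(space, f)
}

#' Strict local maxima of a tabulated landscape
#'
#' Sequences whose fitness strictly exceeds that of every point-mutation
#' neighbor. On a constant landscape there are none.
#'
#' @param land A [tabulated_landscape()].
#' @return Character vector of local-maximum sequences.
#' @export
find_local_maxima <- function(land) {
  space <- attr(land, "space")
  idx <- neighbor_index(space)
  f <- land$fitness
  best_nb <- rep(-Inf, nrow(land))
  for (j in seq_len(ncol(idx))) {
    jj <- idx[, j]
    ok <- jj > 0L
    best_nb[ok] <- pmax(best_nb[ok], f[jj[ok]])
  }
  land$sequence[f > best_nb]
}

# for every sequence, the index of its greedy-ascent local maximum
basin_map <- function(land) {
  space <- attr(land, "space")
  idx <- neighbor_index(space)
  f <- land$fitness
  n <- nrow(land)
  nf <- matrix(-Inf, n, ncol(idx))
  for (j in seq_len(ncol(idx))) {
    jj <- idx[, j]
    ok <- jj > 0L
    nf[ok, j] <- f[jj[ok]]
  }
  best_col <- max.col(nf, ties.method = "first")
  best_fit <- nf[cbind(seq_len(n), best_col)]
  nxt <- seq_len(n)
  improving <- best_fit > f
  nxt[improving] <- idx[cbind(which(improving), best_col[improving])]
  # pointer jumping: strict ascent guarantees convergence
  repeat {
    nxt2 <- nxt[nxt]
    if (identical(nxt2, nxt)) break
    nxt <- nxt2
  }
  nxt
}

#' Greedy adaptive ascent to a local maximum
#'
#' Repeatedly moves to the strictly best improving neighbor (ties broken by
#' the deterministic neighbor order) until no neighbor improves. The set of
#' sequences ascending to a given local maximum is that maximum's basin — the
#' operational reading of a "mountain range".
#'
#' @param land A [tabulated_landscape()].
#' @param s Starting sequence.
#' @return The local-maximum sequence reached (possibly `s` itself).
#' @export
greedy_basin <- function(land, s) {
  space <- attr(land, "space")
  check_sequence(s, space)
  cur <- s
  f <- stats::setNames(land$fitness, land$sequence)
  repeat {
    nb <- seq_neighbors(cur, space)
    fits <- f[nb]
    best <- which.max(fits)
    if (fits[best] <= f[cur]) return(cur)
    cur <- nb[best]
  }
}

#' Basin decomposition of a landscape
#'
#' @param land A [tabulated_landscape()].
#' @return Tibble with columns `sequence`, `basin` (the local maximum each
#'   sequence greedily ascends to). Basins partition the space.
#' @export
greedy_basins <- function(land) {
  nxt <- basin_map(land)
  tibble::tibble(sequence = land$sequence, basin = land$sequence[nxt])
}

# ---- the two approximation operators --------------------------------------

new_approximation <- function(land, target, f_star, f_max, kind) {
  if (length(target) == 0)
    stop("empty target set: no sequence reaches fitness threshold f* = ",
         f_star, " (discovery undefined)", call. = FALSE)
  structure(list(landscape = land, target = target, f_star = f_star,
                 f_max = f_max, kind = kind),
            class = "pw_approximation")
}

#' @export
print.pw_approximation <- function(x, ...) {
  cat("<", x$kind, " approximation> f* = ", x$f_star,
      ", |target| = ", length(x$target), " of ", nrow(x$landscape),
      if (!is.na(x$f_max)) paste0(", f_max = ", signif(x$f_max, 4)),
      "\n", sep = "")
  invisible(x)
}

#' Step-function (threshold) approximation of a rugged landscape
#'
#' Sequences with fitness below a threshold `f_star` cannot be acted on by
#' selection and are treated as neutral background (fitness 1); sequences at
#' or above `f_star` form the target set and receive a common advantageous
#' fitness. The rugged landscape collapses to a binary broad-peak-style one.
#'
#' @param land A [tabulated_landscape()].
#' @param f_star Fitness threshold defining function.
#' @param target_fitness Common fitness assigned to the target set (> 1).
#' @return A `pw_approximation`: the binarized landscape (with
#'   `attr(, "target")` set) plus the target sequences. Errors if the target
#'   set is empty.
#' @export
approximate_threshold <- function(land, f_star, target_fitness = 2) {
  stopifnot(target_fitness > 1)
  in_target <- land$fitness >= f_star
  target <- land$sequence[in_target]
  out <- land
  out$fitness <- ifelse(in_target, target_fitness, 1)
  attr(out, "target") <- target
  new_approximation(out, target, f_star, NA_real_, "threshold")
}

#' Plateau (mountain-range) approximation of a rugged landscape
#'
#' Local maxima below the threshold trap the evolutionary walk. This
#' approximation declares every sequence whose greedy-ascent basin peaks at or
#' above `f_star` a target (the target set starts at the upslope of a
#' sufficiently high mountain range), and lifts the entire complement to the
#' flat level `f_max` — the fitness of the highest local maximum below
#' `f_star`. Target fitness values are left untouched. Every threshold target
#' is also a plateau target, so this approximation is the more lenient one.
#'
#' @inheritParams approximate_threshold
#' @return A `pw_approximation` with `f_max` filled in.
#' @export
approximate_plateau <- function(land, f_star) {
  nxt <- basin_map(land)
  peak_fit <- land$fitness[nxt]
  in_target <- peak_fit >= f_star
  target <- land$sequence[in_target]
  maxima <- unique(nxt)
  sub <- land$fitness[maxima][land$fitness[maxima] < f_star]
  f_max <- if (length(sub)) max(sub) else NA_real_
  out <- land
  if (any(!in_target)) out$fitness[!in_target] <- f_max
  attr(out, "target") <- target
  new_approximation(out, target, f_star, f_max, "plateau")
}

# ---- plain-text landscape I/O ---------------------------------------------

#' Write / read a tabulated landscape as two-column text
#'
#' Plain TSV with a header line carrying `L` and the alphabet, then one
#' `sequence<TAB>fitness` row per genotype.
#'
#' @param land A [tabulated_landscape()].
#' @param path Output file path.
#' @export
write_landscape <- function(land, path) {
  space <- attr(land, "space")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#peakwalk L=%d alphabet=%s", space$L,
                     paste(space$alphabet, collapse = "")), con)
  writeLines("sequence\tfitness", con)
  writeLines(sprintf("%s\t%.17g", land$sequence, land$fitness), con)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("^#peakwalk L=(\\d+) alphabet=(\\S+)$", hdr))[[1]]
  if (length(m) != 3) stop("not a peakwalk landscape file: bad header")
  space <- seq_space(as.integer(m[2]),
                     alphabet = strsplit(m[3], "", fixed = TRUE)[[1]])
  tbl <- utils::read.delim(path, skip = 1, colClasses = c("character", "numeric"))
  f <- stats::setNames(tbl$fitness, tbl$sequence)
  tabulated_landscape(space, f)
}
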