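#' Parse a +/-1 charge string
#'
#' Charge sequences are written in the compact notation used throughout the
#' package: `"1"` for a favorable unit charge, `"-1"` for an antagonistic
#' one, e.g. `"11-11"` is the four-monomer chain (+1, +1, -1, +1).
#' Whitespace is ignored. Index 1 of the result is the *head* monomer, the
#' first to exit on the receiving side of the pore.
#'
#' @param text A charge string containing only `1`, `-1` and whitespace.
#' @param min_length Minimum accepted chain length; the pore holds five
#'   monomers so anything shorter cannot engage. Set to 1 to disable.
#' @return An integer vector of +1/-1 charges.
#' @examples
#' parse_charges("11-1")
#' @export
parse_charges <- function(text, min_length = 5L) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(gsub("[[:space:]]", "", text), "")[[1]]
  n <- length(chars)
  out <- integer(0)
  i <- 1L
  while (i <= n) {
    if (chars[i] == "1") {
      out <- c(out, 1L)
      i <- i + 1L
    } else if (chars[i] == "-") {
      if (i == n || chars[i + 1L] != "1") {
        stop("malformed charge token at position ", i,
             ": '-' must be followed by '1'", call. = FALSE)
      }
      out <- c(out, -1L)
      i <- i + 2L
    } else {
      stop("unexpected character '", chars[i], "' at position ", i,
           call. = FALSE)
    }
  }
  if (length(out) < min_length) {
    stop("sequence has ", length(out), " charges; at least ", min_length,
         " are required to fill the pore", call. = FALSE)
  }
  out
}

#' Format charges back into the +/-1 string notation
#'
#' Inverse of [parse_charges()].
#'
#' @param charges Integer vector of +1/-1 charges.
#' @return A single string.
#' @export
format_charges <- function(charges) {
  check_charges(charges, min_length = 1L)
  paste0(ifelse(charges > 0, "1", "-1"), collapse = "")
}

check_charges <- function(charges, min_length = 5L) {
  if (!is.numeric(charges) || !all(charges %in% c(-1L, 1L))) {
    stop("charges must be a vector of +1/-1 values", call. = FALSE)
  }
  if (length(charges) < min_length) {
    stop("sequence has ", length(charges), " charges; at least ", min_length,
         " are required", call. = FALSE)
  }
  invisible(as.integer(charges))
}

#' Sequence descriptors: net, head and minimum-window charge
#'
#' `net_charge()` is the total charge Q. `head_charge()` is Qh, the net
#' charge of the first `window` monomers of the translocating edge.
#' `min_window_charge()` is Qmin, the minimum net charge over all
#' contiguous windows of pore length (`window` monomers); it flags the
#' worst antagonistic block the pore will have to hold at once.
#'
#' @param charges Integer vector of +1/-1 charges.
#' @param window Window length in monomers; defaults to the 5-monomer pore.
#' @return An integer.
#' @examples
#' q <- parse_charges("11-111-111-111-111-111-111")
#' net_charge(q)        # 8
#' head_charge(q)       # 3
#' min_window_charge(q) # 1
#' @export
net_charge <- function(charges) {
  check_charges(charges, min_length = 1L)
  as.integer(sum(charges))
}

#' @rdname net_charge
#' @export
head_charge <- function(charges, window = 5L) {
  check_charges(charges, min_length = 1L)
  if (window > length(charges)) {
    stop("window (", window, ") exceeds sequence length (",
         length(charges), ")", call. = FALSE)
  }
  as.integer(sum(charges[seq_len(window)]))
}

#' @rdname net_charge
#' @export
min_window_charge <- function(charges, window = 5L) {
  check_charges(charges, min_length = 1L)
  n <- length(charges)
  if (window > n) {
    stop("window (", window, ") exceeds sequence length (", n, ")",
         call. = FALSE)
  }
  sums <- stats::filter(charges, rep(1, window), sides = 1)[window:n]
  as.integer(min(sums))
}

#' Reverse a charge sequence
#'
#' Engaging a chain from its other end is modelled by reversing the charge
#' order: the old tail becomes the new head.
#'
#' @param charges Integer vector of +1/-1 charges.
#' @return The reversed integer vector.
#' @export
reverse_charges <- function(charges) {
  check_charges(charges, min_length = 1L)
  rev(charges)
}

new_sequence_tbl <- function(id, seq) {
  tibble::tibble(
    id = as.character(id),
    seq = seq,
    N = purrr::map_int(seq, length),
    Q = purrr::map_int(seq, net_charge),
    Qh = purrr::map_int(seq, head_charge),
    Qmin = purrr::map_int(seq, min_window_charge)
  )
}

#' Build a sequence table from charge strings
#'
#' The package passes sequence ensembles around as tibbles with one row per
#' sequence: an `id`, a `seq` list-column of +1/-1 integer vectors, and the
#' descriptors `N`, `Q` (net charge), `Qh` (head-window charge) and `Qmin`
#' (minimum pore-window charge).
#'
#' @param x Character vector of charge strings, or a list of +1/-1 integer
#'   vectors.
#' @param id Optional character vector of ids; defaults to `s1`, `s2`, ...
#' @return A sequence tibble.
#' @examples
#' sequence_tbl(c(a = "11-111", b = "-11111"))
#' @export
sequence_tbl <- function(x, id = NULL) {
  if (is.character(x)) {
    seq <- purrr::map(unname(x), parse_charges)
    if (is.null(id)) id <- names(x)
  } else if (is.list(x)) {
    seq <- purrr::map(unname(x), check_charges)
    if (is.null(id)) id <- names(x)
  } else {
    stop("x must be a character vector or a list of charge vectors",
         call. = FALSE)
  }
  if (is.null(id)) id <- paste0("s", seq_along(seq))
  new_sequence_tbl(id, seq)
}

#' Reverse every sequence in a sequence table
#'
#' @param sequences A sequence tibble (see [sequence_tbl()]).
#' @param suffix Appended to each id to mark the reversal.
#' @return A sequence tibble with reversed charges and refreshed descriptors.
#' @export
reverse_sequences <- function(sequences, suffix = "_rev") {
  new_sequence_tbl(paste0(sequences$id, suffix),
                   purrr::map(sequences$seq, rev))
}

#' Enumerate all charge sequences of length N
#'
#' With `Q = NULL`, yields all `2^N` sequences in binary-counting order
#' (bit 0 = head monomer, bit value 1 = favorable charge). With a net
#' charge `Q`, yields exactly the `choose(N, (N - Q)/2)` sequences of that
#' composition, enumerated by the positions of the antagonistic charges.
#'
#' @param N Chain length (>= 5).
#' @param Q Optional net charge to restrict to; must satisfy `|Q| <= N` and
#'   `Q == N (mod 2)`.
#' @param max_N Guard on the full enumeration size (default 16, i.e. 65,536
#'   sequences); raise explicitly for larger N.
#' @return A sequence tibble.
#' @examples
#' nrow(enumerate_sequences(5))      # 32
#' nrow(enumerate_sequences(20, Q = 16)) # choose(20, 2) = 190
#' @export
enumerate_sequences <- function(N, Q = NULL, max_N = 16L) {
  stopifnot(N >= 5)
  if (!is.null(Q)) {
    check_feasible_Q(N, Q)
    k <- (N - Q) / 2L # antagonistic count
    if (k == 0L) {
      return(new_sequence_tbl("q1", list(rep(1L, N))))
    }
    pos <- utils::combn(N, k)
    seqs <- purrr::map(seq_len(ncol(pos)), function(j) {
      s <- rep(1L, N)
      s[pos[, j]] <- -1L
      s
    })
    return(new_sequence_tbl(paste0("q", seq_along(seqs)), seqs))
  }
  if (N > max_N) {
    stop("full enumeration of 2^", N, " sequences refused; ",
         "raise max_N explicitly if you mean it", call. = FALSE)
  }
  idx <- 0:(2^N - 1)
  seqs <- purrr::map(idx, function(v) {
    bits <- bitwAnd(bitwShiftR(v, 0:(N - 1)), 1L)
    ifelse(bits == 1L, 1L, -1L)
  })
  new_sequence_tbl(paste0("e", idx), seqs)
}

check_feasible_Q <- function(N, Q) {
  if (abs(Q) > N || (N - Q) %% 2L != 0L) {
    stop("net charge Q = ", Q, " is infeasible for N = ", N,
         " (need |Q| <= N and Q == N mod 2)", call. = FALSE)
  }
}

#' Sample random charge sequences
#'
#' Unconstrained sampling draws each site independently +1 or -1 with
#' probability 1/2 (the disordered polyampholyte ensemble). With `Q` given,
#' sequences are uniform random shuffles of the fixed composition
#' `(N + Q)/2` favorable and `(N - Q)/2` antagonistic charges, so every
#' sample has exactly net charge Q.
#'
#' @param N Chain length.
#' @param count Number of sequences.
#' @param seed Integer seed; sampling is reproducible.
#' @param Q Optional exact net charge.
#' @return A sequence tibble.
#' @export
sample_sequences <- function(N, count, seed, Q = NULL) {
  stopifnot(N >= 5, count >= 1)
  rs <- local_rng(seed)
  on.exit(rs())
  if (is.null(Q)) {
    seqs <- purrr::map(seq_len(count), function(k) {
      sample(c(-1L, 1L), N, replace = TRUE)
    })
  } else {
    check_feasible_Q(N, Q)
    base <- c(rep(1L, (N + Q) / 2L), rep(-1L, (N - Q) / 2L))
    seqs <- purrr::map(seq_len(count), function(k) sample(base))
  }
  new_sequence_tbl(paste0("r", seq_len(count)), seqs)
}

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Amino-acid to unit-charge mapping
#'
#' Default mapping for reducing a protein to its charged residues: aspartate
#' and glutamate are acidic (-1), lysine and arginine basic (+1), histidine
#' is dropped (its protonation near neutral pH is ambiguous), and all other
#' residues are neutral and dropped.
#'
#' @param positive,negative,drop Character vectors of one-letter codes.
#' @return A named integer vector over the 20 standard codes; `NA` marks
#'   dropped residues.
#' @export
charge_mapping <- function(positive = c("K", "R"),
                           negative = c("D", "E"),
                           drop = "H") {
  codes <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
             "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- stats::setNames(rep(NA_integer_, length(codes)), codes)
  m[positive] <- 1L
  m[negative] <- -1L
  m[drop] <- NA_integer_
  m
}

#' Reduce a protein sequence to its charge sequence
#'
#' Keeps only charged residues, in order, as +/-1 charges. By default the
#' result is in physical sign convention (acidic = -1). Because the package
#' writes sequences in *favorable units* (+1 = favorable for translocation),
#' pass `favorable_sign = -1` when the acidic residues are the favorably
#' driven species (as for anions moving cis-to-trans under +150 mV), which
#' flips the sign of every charge.
#'
#' @param aa Amino-acid string (one-letter codes) or vector of single codes.
#' @param mapping A mapping from [charge_mapping()].
#' @param favorable_sign +1 to keep physical signs, -1 to flip so the
#'   negative species becomes the favorable +1.
#' @return Integer vector of +1/-1 charges in favorable units.
#' @export
reduce_protein <- function(aa, mapping = charge_mapping(),
                           favorable_sign = 1L) {
  stopifnot(favorable_sign %in% c(-1L, 1L))
  if (length(aa) == 1L) aa <- strsplit(toupper(aa), "")[[1]] else aa <- toupper(aa)
  unknown <- setdiff(unique(aa), names(mapping))
  if (length(unknown)) {
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  q <- mapping[aa]
  q <- as.integer(q[!is.na(q)]) * as.integer(favorable_sign)
  if (length(q) < 5L) {
    stop("only ", length(q), " charged residues; at least 5 are required",
         call. = FALSE)
  }
  unname(q)
}

#' Reference sequence panel
#'
#' Nine N = 20, Q = 8 benchmark sequences (a regular arrangement and
#' variants carrying one to three antagonistic blocks, plus reversals) and
#' the two engagements (h, i) of the charged-residue reduction of the IDP
#' integrase IN (N = 16, Q = 4). These are the single-sequence benchmarks
#' used throughout the tests and the worked examples.
#'
#' @return A sequence tibble with ids `a` to `i`.
#' @export
reference_sequences <- function() {
  sequence_tbl(c(
    a = "11-111-111-111-111-111-111",
    b = "11-1-11111-1111-111-11-111",
    c = "11-11-111-1111-11111-1-111",
    d = "11-1-11111-1-111-111-11111",
    e = "11-1-1111-1-11111-1-111111",
    f = "111-1-1-111-11111-11111-11",
    g = "111-11111-1111-1111-1-1-11",
    h = "11-1111-1-11-111-1-111",
    i = "11-1-111-11-1-1111-111"
  ))
}
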