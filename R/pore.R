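#' Free-energy profile of the alpha-hemolysin pore
#'
#' The pore is modelled as seven axial sites spaced one monomer length
#' (a = 2 nm) apart, spanning the roughly 10 nm channel plus one boundary
#' site at each mouth. `cation` and `anion` give the small-ion free energies
#' (in kBT, +150 mV applied to the trans side) at the tabulated positions
#' -a, 0, a, ..., 5a, where the position axis runs from the *trans*
#' boundary (-a) to the *cis* boundary (5a). The anion values are referenced
#' to the trans-side solution and the cation values to the cis-side
#' solution; `V` is the potential energy of a unit positive charge in the
#' trans bulk relative to the cis bulk (e * 150 mV / kBT at 298 K = 5.84).
#'
#' With those references the tabulated values join their bulk limits
#' continuously at both mouths: relative to the cis bulk the effective
#' cation profile rises almost linearly from 0.07 at the cis edge to 5.53
#' at the trans edge (a near-uniform opposing force), while the effective
#' anion profile is a modest mid-pore barrier ending at -5.77 at the trans
#' edge, so nearly the whole anion driving force is released in the final
#' exit step - the known localization of the translocation force at the
#' trans mouth of alpha-hemolysin.
#'
#' @param cation,anion Seven free energies in kBT at positions -a..5a
#'   (trans-to-cis order).
#' @param V Trans-bulk potential offset for a unit positive charge, kBT.
#' @param polarity Label for the applied potential; only "+150mV" tables
#'   are bundled. Supply your own `cation`/`anion` for other polarities.
#' @param cation_ref,anion_ref Which bulk solution each tabulated row is
#'   referenced to (`"cis"` or `"trans"`); the defaults are the references
#'   under which the bundled +150 mV rows join their bulk limits
#'   continuously.
#' @return A `patrans_profile` object.
#' @examples
#' pore_profile()
#' @export
pore_profile <- function(cation = c(5.53, 6.98, 5.00, 4.65, 1.59, 2.32, 0.07),
                         anion = c(0.07, 3.35, 8.82, 9.08, 7.47, 7.00, 5.87),
                         V = 5.84,
                         polarity = "+150mV",
                         cation_ref = "cis",
                         anion_ref = "trans") {
  stopifnot(length(cation) == 7L, length(anion) == 7L,
            is.finite(V), all(is.finite(cation)), all(is.finite(anion)))
  cation_ref <- match.arg(cation_ref, c("cis", "trans"))
  anion_ref <- match.arg(anion_ref, c("cis", "trans"))
  if (!identical(polarity, "+150mV") &&
      missing(cation) && missing(anion)) {
    stop("only the +150mV profile is bundled; supply cation/anion tables ",
         "for polarity ", polarity, call. = FALSE)
  }
  # trans-bulk energies relative to the cis bulk
  bulk <- c(cation = V, anion = -V)
  structure(
    list(
      table = tibble::tibble(
        position = c("-a", "0", "a", "2a", "3a", "4a", "5a"),
        cation = cation,
        anion = anion
      ),
      # effective per-site energies relative to the cis bulk, indexed by the
      # cis-anchored site coordinate s = -1..5 (s = -1 at the cis mouth):
      # reverse the trans-to-cis rows and re-reference any trans-anchored
      # row to the cis solution by adding that species' trans-bulk energy.
      cation_eff = rev(cation) + if (cation_ref == "trans") unname(bulk["cation"]) else 0,
      anion_eff = rev(anion) + if (anion_ref == "trans") unname(bulk["anion"]) else 0,
      V = V,
      polarity = polarity,
      cation_ref = cation_ref,
      anion_ref = anion_ref
    ),
    class = "patrans_profile"
  )
}

#' @export
print.patrans_profile <- function(x, ...) {
  cat("alpha-hemolysin free-energy profile (", x$polarity, ", V = ",
      format(x$V), " kBT)\n", sep = "")
  print(x$table)
  invisible(x)
}

directions <- c("cis_to_trans", "trans_to_cis")

check_direction <- function(direction) {
  match.arg(direction, directions)
}

#' Axial site occupied by a monomer at a given chain offset
#'
#' Sites are counted from the cis mouth: s = -1..5 are the tabulated pore
#' sites, s < -1 is cis bulk and s > 5 trans bulk. The chain offset x is
#' the net number of accepted forward hops since engagement. At x = 0 the
#' five pore sites 0..4 hold monomers 4..0 for cis-to-trans engagement
#' (head at site 4, one hop from the trans mouth) and monomers 0..4 for the
#' reverse direction (head at site 0, one hop from the cis mouth); the
#' sixth monomer sits on the boundary site in either case.
#'
#' @param i Monomer index, 0-based from the head.
#' @param x Chain offset.
#' @param direction `"cis_to_trans"` or `"trans_to_cis"`.
#' @return Integer site coordinate(s).
#' @export
monomer_site <- function(i, x, direction = "cis_to_trans") {
  direction <- check_direction(direction)
  if (direction == "cis_to_trans") (4L + x) - i else i - x
}

#' Free energy of one monomer at one site
#'
#' Charges are in favorable units: +1 is the species favorably driven in
#' the given direction (the anion for cis-to-trans under +150 mV, the
#' cation for trans-to-cis). Energies are relative to the cis bulk.
#'
#' @param q Charge in favorable units (+1 or -1).
#' @param s Site coordinate (cis-anchored, see [monomer_site()]).
#' @param direction Engagement direction.
#' @param profile A [pore_profile()].
#' @return Energy in kBT.
#' @export
monomer_energy <- function(q, s, direction = "cis_to_trans",
                           profile = pore_profile()) {
  direction <- check_direction(direction)
  check_charges(q, min_length = 1L)
  n <- max(length(q), length(s))
  q <- rep_len(q, n)
  s <- rep_len(s, n)
  is_anion <- if (direction == "cis_to_trans") q > 0 else q < 0
  V <- profile$V
  out <- numeric(n)
  hi <- s > 5
  mid <- s >= -1 & !hi
  out[hi] <- ifelse(is_anion[hi], -V, V)
  out[mid] <- ifelse(is_anion[mid],
                     profile$anion_eff[s[mid] + 2L],
                     profile$cation_eff[s[mid] + 2L])
  out
}

#' Total chain free energy at a given offset
#'
#' Sum of [monomer_energy()] over all monomers, the quantity whose
#' differences drive the Metropolis dynamics.
#'
#' @param charges Integer vector of +1/-1 charges (favorable units).
#' @inheritParams monomer_energy
#' @param x Chain offset.
#' @return Energy in kBT.
#' @export
chain_energy <- function(charges, x, direction = "cis_to_trans",
                         profile = pore_profile()) {
  check_charges(charges, min_length = 1L)
  direction <- check_direction(direction)
  vapply(x, function(xx) {
    s <- monomer_site(seq_along(charges) - 1L, xx, direction)
    sum(monomer_energy(charges, s, direction, profile))
  }, 0)
}

#' Precompute the full energy landscape of a sequence
#'
#' Tabulates E(x) for every offset x = -6..N+1. Offsets -5..N are the
#' transient states; x = -6 (whole chain back in the engagement-side bulk)
#' absorbs as rejection and x = N+1 (tail past the far mouth) as
#' translocation.
#'
#' @param charges A +/-1 charge vector or a single-row of a sequence tibble.
#' @inheritParams monomer_energy
#' @param id Optional label carried through to results.
#' @return A `patrans_landscape` object: energies, offsets, N, direction.
#' @examples
#' l <- build_landscape(parse_charges("11-111-111-111-111-111-111"))
#' plot_landscape(l)
#' @export
build_landscape <- function(charges, direction = "cis_to_trans",
                            profile = pore_profile(), id = NULL) {
  charges <- check_charges(charges)
  direction <- check_direction(direction)
  N <- length(charges)
  offsets <- (-6L):(N + 1L)
  # vectorized over the (offset, monomer) grid
  i <- seq_len(N) - 1L
  smat <- outer(offsets, i, function(x, ii) monomer_site(ii, x, direction))
  is_anion <- if (direction == "cis_to_trans") charges > 0 else charges < 0
  V <- profile$V
  emat <- matrix(0, nrow = length(offsets), ncol = N)
  for (k in seq_len(N)) {
    s <- smat[, k]
    col <- if (is_anion[k]) profile$anion_eff else profile$cation_eff
    bulkR <- if (is_anion[k]) -V else V
    emat[, k] <- ifelse(s < -1, 0, ifelse(s > 5, bulkR, col[pmin(pmax(s, -1), 5) + 2L]))
  }
  structure(
    list(
      E = rowSums(emat),
      offsets = offsets,
      N = N,
      direction = direction,
      charges = charges,
      V = V,
      id = id %||% format_charges(charges)
    ),
    class = "patrans_landscape"
  )
}

#' @export
print.patrans_landscape <- function(x, ...) {
  cat("translocation landscape: N =", x$N, "(", x$direction, ")\n")
  cat("  E(x_rej) =", format(x$E[1]), " E(0) =",
      format(x$E[x$offsets == 0]), " E(x_tr) =",
      format(x$E[length(x$E)]), "kBT\n")
  invisible(x)
}

#' @rdname build_landscape
#' @param landscape A `patrans_landscape`.
#' @export
plot_landscape <- function(landscape) {
  df <- tibble::tibble(x = landscape$offsets, E = landscape$E)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$E)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "chain offset x (hops since engagement)",
                  y = "E(x)  [kBT]",
                  title = landscape$id,
                  subtitle = landscape$direction) +
    ggplot2::theme_minimal()
}

#' Read / write a pore-profile override table
#'
#' Plain TSV with columns `position`, `cation_kBT`, `anion_kBT` (seven rows,
#' trans-to-cis order) and `#`-comment header lines carrying `V` and
#' `polarity`.
#'
#' @param path File path.
#' @return `read_profile()` returns a [pore_profile()].
#' @export
read_profile <- function(path) {
  hdr <- grep("^#", readLines(path), value = TRUE)
  pick <- function(key, default) {
    ln <- grep(paste0(key, "="), hdr, value = TRUE)
    if (!length(ln)) return(default)
    sub(paste0(".*", key, "=([^ ]+).*"), "\\1", ln[1])
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 7L)
  pore_profile(cation = tab$cation_kBT, anion = tab$anion_kBT,
               V = as.numeric(pick("V", "5.84")),
               polarity = pick("polarity", "+150mV"),
               cation_ref = pick("cation_ref", "cis"),
               anion_ref = pick("anion_ref", "trans"))
}

#' @rdname read_profile
#' @param profile A [pore_profile()].
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# patrans pore profile; V=", format(profile$V),
           " polarity=", profile$polarity,
           " cation_ref=", profile$cation_ref,
           " anion_ref=", profile$anion_ref),
    "position\tcation_kBT\tanion_kBT"
  ), con)
  utils::write.table(
    data.frame(position = profile$table$position,
               cation_kBT = profile$table$cation,
               anion_kBT = profile$table$anion),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
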