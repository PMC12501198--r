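# The sixteen-atom decomposition of time-delayed mutual information, the
# six-mode taxonomy, and the classical information-dynamics measures it
# explains (AIS, TE, whole-minus-sum and revised Phi, causal density).

TAXONOMY_MODES <- list(
  storage  = c("red->red", "un1->un1", "un2->un2", "syn->syn"),
  copy     = c("un1->red", "un2->red"),
  transfer = c("un1->un2", "un2->un1"),
  erasure  = c("red->un1", "red->un2"),
  downward = c("syn->un1", "syn->un2", "syn->red"),
  upward   = c("un1->syn", "un2->syn", "red->syn")
)

AIS_ATOMS <- list(
  `1` = c("red->red", "red->un1", "un1->red", "un1->un1"),
  `2` = c("red->red", "red->un2", "un2->red", "un2->un2")
)

TE_ATOMS <- list(
  "1to2" = c("syn->red", "syn->un2", "un1->red", "un1->un2"),
  "2to1" = c("syn->red", "syn->un1", "un2->red", "un2->un1")
)

# Atom membership of whole-minus-sum Phi: minus the double-redundancy atom,
# plus the two cross-unique (transfer) atoms, plus every synergy-involving atom.
PHI_WMS_WEIGHTS <- c(
  "red->red" = -1, "un1->un2" = 1, "un2->un1" = 1,
  "red->syn" = 1, "un1->syn" = 1, "un2->syn" = 1, "syn->syn" = 1,
  "syn->red" = 1, "syn->un1" = 1, "syn->un2" = 1
)

# Accept a phiid fit, a named atom vector, or a tidy atom table.
atom_vector <- function(atoms) {
  if (inherits(atoms, "phiid")) return(atoms$atoms)
  if (is.data.frame(atoms)) {
    atoms <- stats::setNames(atoms$value, atoms$label)
  }
  labs <- phiid_atom_labels()
  if (!all(labs %in% names(atoms))) {
    stop("`atoms` must provide all 16 atom labels.", call. = FALSE)
  }
  atoms[labs]
}

#' Integrated information decomposition of a two-part system
#'
#' Computes the sixteen information atoms of a bipartite dynamical system:
#' the redundancy table from the chosen backend is Moebius-inverted over the
#' product lattice, and the classical information-dynamics measures are
#' evaluated directly from mutual informations. The atoms sum to the
#' time-delayed mutual information.
#'
#' @param system A [discrete_system()] or [gaussian_system()].
#' @param redundancy Double-redundancy backend, `"mmi"` or `"ccs"`.
#' @return An object of class `phiid` with elements `atoms` (named vector of
#'   16 atoms, bits), `redundancies`, `measures` (list of derived measures),
#'   `backend` and `system`. Use [tidy()][generics::tidy] for a tibble of
#'   atoms, [glance()][generics::glance] for the one-row measure summary and
#'   `autoplot()` for the 4x4 atom matrix.
#' @examples
#' fit <- phiid_decompose(make_copy_system())
#' tidy(fit)
#' glance(fit)
#' @export
phiid_decompose <- function(system, redundancy = c("mmi", "ccs")) {
  redundancy <- match.arg(redundancy)
  lat <- bipartite_lattice()
  red <- redundancy_table(system, redundancy, lat)
  atoms <- moebius_atoms(lat, red)
  fit <- structure(list(atoms = atoms, redundancies = red,
                        backend = redundancy, system = system),
                   class = "phiid")
  fit$measures <- compute_measures(fit)
  fit
}

compute_measures <- function(fit) {
  system <- fit$system
  te12 <- cond_mutual_info(system, "x1", "y2", "x2")
  te21 <- cond_mutual_info(system, "x2", "y1", "x1")
  ucd <- te12 + te21
  modes <- taxonomy_modes(fit$atoms)
  c(list(
    tdmi = mutual_info(system, c("x1", "x2"), c("y1", "y2")),
    ais_1 = mutual_info(system, "x1", "y1"),
    ais_2 = mutual_info(system, "x2", "y2"),
    te_1to2 = te12,
    te_2to1 = te21,
    phi_wms = phi_wms(system),
    phi_r = phi_r(system, fit$backend),
    ucd = ucd,
    cd_corrected = ucd - unname(fit$atoms["syn->red"])
  ), as.list(modes))
}

#' @export
print.phiid <- function(x, digits = 4, ...) {
  cat("Integrated information decomposition (", x$backend, " backend)\n",
      sep = "")
  cat("TDMI: ", round(x$measures$tdmi, digits), " bits\n\n", sep = "")
  m <- matrix(x$atoms, 4, 4, byrow = TRUE,
              dimnames = list(paste0(c("red", "un1", "un2", "syn"), "->"),
                              c("red", "un1", "un2", "syn")))
  print(round(m, digits))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the sixteen atoms of a decomposition
#'
#' @param x A `phiid` object.
#' @param ... Unused.
#' @return A tibble with columns `past`, `future`, `label`, `value` (bits)
#'   and `mode` (the taxonomy mode the atom belongs to).
#' @export
tidy.phiid <- function(x, ...) {
  labs <- phiid_atom_labels()
  parts <- strsplit(labs, "->", fixed = TRUE)
  mode_of <- stats::setNames(
    rep(names(TAXONOMY_MODES), lengths(TAXONOMY_MODES)),
    unlist(TAXONOMY_MODES))
  tibble::tibble(
    past = vapply(parts, `[`, "", 1),
    future = vapply(parts, `[`, "", 2),
    label = labs,
    value = unname(x$atoms[labs]),
    mode = unname(mode_of[labs])
  )
}

#' One-row summary of all derived measures
#'
#' @param x A `phiid` object.
#' @param ... Unused.
#' @return A one-row tibble with the time-delayed mutual information, per-part
#'   active information storage, both transfer entropies, whole-minus-sum and
#'   revised integrated information, raw and corrected causal density, and
#'   the six taxonomy-mode aggregates.
#' @export
glance.phiid <- function(x, ...) {
  tibble::as_tibble(x$measures)
}

#' Plot the atom matrix of a decomposition
#'
#' Displays the sixteen atoms as a past-by-future matrix of tiles, the
#' standard presentation of the bipartite decomposition.
#'
#' @param object A `phiid` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phiid <- function(object, ...) {
  d <- tidy(object)
  d$past <- factor(d$past, levels = c("red", "un1", "un2", "syn"))
  d$future <- factor(d$future, levels = c("red", "un1", "un2", "syn"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$future, y = .data$past,
                                  fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$value)),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev(c("red", "un1", "un2", "syn"))) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "future", y = "past", fill = "bits",
                  title = "Information atoms") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Active information storage as an atom aggregate
#'
#' Sums the four atoms that make up `I(X_i[t]; X_i[t+1])`: redundant and
#' unique information of part `i` that stays redundant or unique to `i`.
#' For any backend satisfying the compatibility axiom this equals the direct
#' mutual information.
#'
#' @param atoms A `phiid` fit, a named atom vector, or a tidy atom table.
#' @param part Which part, `1` or `2`.
#' @return Bits.
#' @export
ais_from_atoms <- function(atoms, part) {
  part <- as.character(part)
  if (!part %in% c("1", "2")) stop("`part` must be 1 or 2.", call. = FALSE)
  sum(atom_vector(atoms)[AIS_ATOMS[[part]]])
}

#' Transfer entropy as an atom aggregate
#'
#' Sums the four atoms that make up `I(X_src[t]; X_tgt[t+1] | X_tgt[t])`:
#' unique or synergistic information in the past that ends up unique to the
#' target or redundant. Only the cross-unique atom is genuine transfer; the
#' others are synergistic or duplicative effects that transfer entropy
#' conflates.
#'
#' @inheritParams ais_from_atoms
#' @param source,target Source and target part (`1` or `2`, distinct).
#' @return Bits.
#' @export
te_from_atoms <- function(atoms, source, target) {
  key <- paste0(source, "to", target)
  if (!key %in% names(TE_ATOMS)) {
    stop("`source` and `target` must be distinct parts (1 or 2).",
         call. = FALSE)
  }
  sum(atom_vector(atoms)[TE_ATOMS[[key]]])
}

#' Whole-minus-sum integrated information
#'
#' The time-delayed mutual information of the whole system minus the sum of
#' the per-part self-informations. In atom terms it counts every
#' synergy-involving atom and both cross-unique atoms positively and the
#' double-redundancy atom negatively, which is why it can be negative in
#' redundancy-dominated systems.
#'
#' @param system A [discrete_system()] or [gaussian_system()].
#' @return Bits (may be negative).
#' @export
phi_wms <- function(system) {
  mutual_info(system, c("x1", "x2"), c("y1", "y2")) -
    mutual_info(system, "x1", "y1") -
    mutual_info(system, "x2", "y2")
}

#' Revised integrated information
#'
#' Whole-minus-sum integrated information with the double-redundancy added
#' back, removing its negative contribution. Under the MMI backend the
#' double-redundancy is the minimum of the four pairwise part-to-part mutual
#' informations; under CCS it is the multitarget common-change-in-surprisal
#' value at the bottom lattice node.
#'
#' @inheritParams phi_wms
#' @param redundancy Double-redundancy backend, `"mmi"` or `"ccs"`.
#' @return Bits.
#' @export
phi_r <- function(system, redundancy = c("mmi", "ccs")) {
  redundancy <- match.arg(redundancy)
  lat <- bipartite_lattice()
  bottom <- lat$nodes[[which(lat$labels == "red->red")]]
  fn <- if (redundancy == "mmi") redundancy_mmi else redundancy_ccs
  phi_wms(system) + fn(system, bottom)
}

#' Causal density, raw and corrected
#'
#' The raw (unnormalised) causal density is the sum of the two transfer
#' entropies; because both directions contain the synergy-to-redundancy atom,
#' it double-counts that atom, and the corrected value subtracts it once.
#'
#' @inheritParams phi_r
#' @return Named list with `ucd` and `cd_corrected`, in bits.
#' @export
causal_density <- function(system, redundancy = c("mmi", "ccs")) {
  fit <- phiid_decompose(system, redundancy)
  list(ucd = fit$measures$ucd, cd_corrected = fit$measures$cd_corrected)
}

#' Six-mode taxonomy of information dynamics
#'
#' Partitions the sixteen atoms into six disjoint aggregates: storage (4
#' atoms), copy (2), transfer (2), erasure (2), downward causation (3) and
#' upward causation (3).
#'
#' @inheritParams ais_from_atoms
#' @return Named numeric vector of six mode totals, in bits.
#' @export
taxonomy_modes <- function(atoms) {
  a <- atom_vector(atoms)
  vapply(TAXONOMY_MODES, function(labs) sum(a[labs]), 0)
}

#' Which atoms are nonzero beyond numerical noise
#'
#' @inheritParams ais_from_atoms
#' @param tol Magnitude threshold (default `1e-10`).
#' @return Named logical vector over the 16 atom labels.
#' @export
nonzero_atoms <- function(atoms, tol = 1e-10) {
  abs(atom_vector(atoms)) > tol
}

#' Serialisable report of a decomposition
#'
#' Flattens a `phiid` fit into the fixed-key list used by [write_report()]
#' and the command-line interface: the derived measures plus an `atoms`
#' sub-map keyed by node label.
#'
#' @param fit A `phiid` object.
#' @return A named list.
#' @export
measure_report <- function(fit) {
  stopifnot(inherits(fit, "phiid"))
  c(fit$measures, list(atoms = as.list(fit$atoms)))
}
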