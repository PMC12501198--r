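# Double-redundancy backends. Both satisfy the compatibility axiom: on nodes
# whose past and future antichains are singletons the value reduces to a
# plain mutual information, and on single-target composite nodes to a
# single-target PID redundancy.

past_group <- function(member) paste0("x", member)
future_group <- function(member) paste0("y", member)

check_node2 <- function(node) {
  stopifnot(inherits(node, "phiid_node"))
  if (node$n_parts != 2) {
    stop("Numeric redundancy evaluation requires a 2-part node.", call. = FALSE)
  }
  node
}

#' Minimum-mutual-information double-redundancy
#'
#' Evaluates the MMI double-redundancy at a product-lattice node: the minimum
#' over all member pairs `(a, b)` of the past and future antichains of the
#' joint-group mutual information `I(X_a; Y_b)`. On singleton nodes this is a
#' plain mutual information, so the compatibility axiom holds by
#' construction. Works for discrete and Gaussian systems and is the default
#' (and, for Gaussian systems, the only) backend.
#'
#' @param system A [discrete_system()] or [gaussian_system()].
#' @param node A bipartite [product_node()].
#' @return Redundancy in bits.
#' @examples
#' lat <- product_lattice(2)
#' redundancy_mmi(make_copy_system(), lat$nodes[[1]])  # bottom node: 0 bits
#' @export
redundancy_mmi <- function(system, node) {
  check_node2(node)
  vals <- c()
  for (a in node$past$members) {
    for (b in node$future$members) {
      vals <- c(vals, mutual_info(system, past_group(a), future_group(b)))
    }
  }
  min(vals)
}

# sign with a tolerance for floating error in local log terms
sgn_tol <- function(x, tol = 1e-10) (x > tol) - (x < -tol)

# Single-target common-change-in-surprisal redundancy of two source groups
# about one target group, evaluated pointwise on the support: the local
# co-information c = i(s1;t) + i(s2;t) - i(s1,s2;t) is counted at a state
# only when i(s1;t), i(s2;t), i(s1,s2;t) and c all share one sign.
ccs_single_target <- function(pmf, src1, src2, target) {
  pos <- pmf$p > 0
  p <- pmf$p[pos]
  l <- function(cols) log2(local_prob(pmf, cols)[pos])
  i1 <- l(c(src1, target)) - l(src1) - l(target)
  i2 <- l(c(src2, target)) - l(src2) - l(target)
  i12 <- l(c(src1, src2, target)) - l(c(src1, src2)) - l(target)
  co <- i1 + i2 - i12
  keep <- sgn_tol(i1) == sgn_tol(i2) & sgn_tol(i2) == sgn_tol(i12) &
    sgn_tol(i12) == sgn_tol(co)
  sum(p * co * keep)
}

# Double (multitarget) CCS redundancy at the bottom node: the local four-way
# co-information, counted when the four pairwise local mutual informations
# i(x_a; y_b) and the co-information itself all share one sign.
ccs_double <- function(pmf) {
  pos <- pmf$p > 0
  p <- pmf$p[pos]
  l <- function(cols) -log2(local_prob(pmf, cols)[pos])
  h1 <- l("x1"); h2 <- l("x2"); h3 <- l("y1"); h4 <- l("y2")
  # inclusion-exclusion over the four slots
  co <- (h1 + h2 + h3 + h4) -
    (l(c("x1", "x2")) + l(c("x1", "y1")) + l(c("x1", "y2")) +
       l(c("x2", "y1")) + l(c("x2", "y2")) + l(c("y1", "y2"))) +
    (l(c("x1", "x2", "y1")) + l(c("x1", "x2", "y2")) +
       l(c("x1", "y1", "y2")) + l(c("x2", "y1", "y2"))) -
    l(c("x1", "x2", "y1", "y2"))
  i11 <- h1 + h3 - l(c("x1", "y1"))
  i12 <- h1 + h4 - l(c("x1", "y2"))
  i21 <- h2 + h3 - l(c("x2", "y1"))
  i22 <- h2 + h4 - l(c("x2", "y2"))
  keep <- sgn_tol(i11) == sgn_tol(i12) & sgn_tol(i12) == sgn_tol(i21) &
    sgn_tol(i21) == sgn_tol(i22) & sgn_tol(i22) == sgn_tol(co)
  sum(p * co * keep)
}

#' Common-change-in-surprisal double-redundancy
#'
#' Evaluates the CCS double-redundancy at a product-lattice node of a
#' discrete system. Singleton nodes reduce to plain mutual information
#' (compatibility axiom); composite-past nodes use the pointwise
#' common-change-in-surprisal PID redundancy of the two parts' pasts about
#' the target group; composite-future nodes use its time reverse; the bottom
#' node uses the multitarget rule based on the four-way local
#' co-information. Local co-information terms are counted only when all
#' constituent local information changes share one sign.
#'
#' Only discrete systems are supported; for Gaussian systems use the MMI
#' backend (into which many PIDs collapse for jointly Gaussian variables).
#'
#' @inheritParams redundancy_mmi
#' @return Redundancy in bits (may be negative at composite nodes).
#' @export
redundancy_ccs <- function(system, node) {
  check_node2(node)
  if (!inherits(system, "phiid_discrete")) {
    stop("CCS redundancy is only defined for discrete systems; ",
         "use redundancy = \"mmi\" for Gaussian systems.", call. = FALSE)
  }
  past_comp <- length(node$past$members) > 1
  fut_comp <- length(node$future$members) > 1
  if (!past_comp && !fut_comp) {
    mutual_info(system, past_group(node$past$members[[1]]),
                future_group(node$future$members[[1]]))
  } else if (past_comp && !fut_comp) {
    ccs_single_target(system, "x1", "x2",
                      future_group(node$future$members[[1]]))
  } else if (!past_comp && fut_comp) {
    ccs_single_target(system, "y1", "y2",
                      past_group(node$past$members[[1]]))
  } else {
    ccs_double(system)
  }
}

#' Assemble the full 16-node redundancy table
#'
#' Evaluates the chosen double-redundancy backend at every node of the
#' bipartite product lattice. The table feeds [moebius_atoms()] to produce
#' the sixteen information atoms.
#'
#' @inheritParams redundancy_mmi
#' @param redundancy Backend: `"mmi"` (discrete or Gaussian) or `"ccs"`
#'   (discrete only).
#' @param lattice A bipartite [product_lattice()]; built internally if not
#'   supplied.
#' @return Named numeric vector of redundancies in bits, one per node label.
#' @export
redundancy_table <- function(system, redundancy = c("mmi", "ccs"),
                             lattice = NULL) {
  redundancy <- match.arg(redundancy)
  if (!is_phiid_system(system)) {
    stop("`system` must be a discrete or Gaussian two-part system.",
         call. = FALSE)
  }
  if (is.null(lattice)) lattice <- bipartite_lattice()
  fn <- if (redundancy == "mmi") redundancy_mmi else redundancy_ccs
  vapply(lattice$nodes, function(nd) fn(system, nd), 0) |>
    stats::setNames(lattice$labels)
}
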