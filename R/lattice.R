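# Redundancy lattice machinery: antichains over part indices, the product
# (double-redundancy) lattice, and Moebius inversion from redundancies to atoms.

#' Construct an antichain of part-index subsets
#'
#' An antichain is a collection of nonempty subsets of `{1, ..., n_parts}` in
#' which no member contains another. Antichains are the nodes of the
#' Williams-Beer redundancy lattice; for a bipartite system the four
#' antichains correspond to redundant (`{1}{2}`), unique (`{1}`, `{2}`) and
#' synergistic (`{12}`) information.
#'
#' Members are canonicalised: elements within a member are sorted, and members
#' are ordered by (size, lexicographic).
#'
#' @param members List of integer vectors, each a nonempty subset of
#'   `1:n_parts`.
#' @param n_parts Number of parts in the system (positive integer).
#' @return An object of class `phiid_antichain`.
#' @examples
#' antichain(list(1, 2), n_parts = 2)   # the "red" node
#' antichain(list(1:2), n_parts = 2)    # the "syn" node
#' @export
antichain <- function(members, n_parts) {
  if (!is.numeric(n_parts) || length(n_parts) != 1 || n_parts < 1 ||
      n_parts != round(n_parts)) {
    stop("`n_parts` must be a positive integer.", call. = FALSE)
  }
  n_parts <- as.integer(n_parts)
  if (!is.list(members)) members <- list(members)
  members <- lapply(members, function(m) sort(unique(as.integer(m))))
  if (length(members) == 0) {
    stop("An antichain must have at least one member.", call. = FALSE)
  }
  for (m in members) {
    if (length(m) == 0) stop("Antichain members must be nonempty.", call. = FALSE)
    if (any(m < 1L | m > n_parts)) {
      stop("Antichain members must be subsets of 1:n_parts.", call. = FALSE)
    }
  }
  np <- length(members)
  if (np > 1) {
    for (i in seq_len(np - 1)) {
      for (j in (i + 1):np) {
        if (all(members[[i]] %in% members[[j]]) ||
            all(members[[j]] %in% members[[i]])) {
          stop("Antichain members must be pairwise incomparable.", call. = FALSE)
        }
      }
    }
  }
  members <- members[order(lengths(members), vapply(members, member_key, ""))]
  structure(list(members = members, n_parts = n_parts),
            class = "phiid_antichain")
}

member_key <- function(m) paste(m, collapse = "")

antichain_key <- function(a) {
  paste0(length(a$members), ":",
         paste(vapply(a$members, function(m) {
           paste0(length(m), member_key(m))
         }, ""), collapse = ","))
}

#' @export
format.phiid_antichain <- function(x, ...) {
  paste(vapply(x$members, function(m) {
    paste0("{", paste(m, collapse = ""), "}")
  }, ""), collapse = "")
}

#' @export
print.phiid_antichain <- function(x, ...) {
  cat("<antichain> ", format(x), "  (n_parts = ", x$n_parts, ")\n", sep = "")
  invisible(x)
}

#' Enumerate all antichains of nonempty subsets
#'
#' Returns every antichain over `{1, ..., n_parts}` (excluding the empty
#' collection) in canonical order: by number of members, then by member
#' structure. For a bipartite system this yields the four nodes of the
#' redundancy lattice, `{1}`, `{2}`, `{12}` and `{1}{2}`; for three parts
#' there are 18 antichains.
#'
#' Enumeration is by exhaustive filtering of all collections of nonempty
#' subsets and is supported for `n_parts <= 4`.
#'
#' @inheritParams antichain
#' @return A list of `phiid_antichain` objects.
#' @export
antichains <- function(n_parts) {
  if (!is.numeric(n_parts) || length(n_parts) != 1 || n_parts < 1 ||
      n_parts != round(n_parts)) {
    stop("`n_parts` must be a positive integer.", call. = FALSE)
  }
  n_parts <- as.integer(n_parts)
  if (n_parts > 4) {
    stop("Antichain enumeration supported for n_parts <= 4.", call. = FALSE)
  }
  subsets <- unlist(lapply(seq_len(n_parts), function(k) {
    m <- utils::combn(n_parts, k)
    lapply(seq_len(ncol(m)), function(i) m[, i])
  }), recursive = FALSE)
  ns <- length(subsets)
  incomparable <- function(sel) {
    if (length(sel) < 2) return(TRUE)
    for (i in seq_along(sel)[-length(sel)]) {
      for (j in (i + 1):length(sel)) {
        a <- subsets[[sel[i]]]; b <- subsets[[sel[j]]]
        if (all(a %in% b) || all(b %in% a)) return(FALSE)
      }
    }
    TRUE
  }
  out <- list()
  for (code in seq_len(2^ns - 1)) {
    sel <- which(bitwAnd(code, 2^(seq_len(ns) - 1)) > 0)
    if (incomparable(sel)) {
      out[[length(out) + 1]] <- antichain(subsets[sel], n_parts)
    }
  }
  out[order(vapply(out, antichain_key, ""))]
}

#' Partial order on the redundancy lattice
#'
#' Tests whether antichain `a` precedes antichain `b`: for every member of `b`
#' there is a member of `a` contained in it (containment taken as non-strict,
#' so the relation is reflexive and the structure is a lattice).
#'
#' @param a,b `phiid_antichain` objects over the same part universe.
#' @return Logical scalar.
#' @export
antichain_below <- function(a, b) {
  stopifnot(inherits(a, "phiid_antichain"), inherits(b, "phiid_antichain"))
  if (a$n_parts != b$n_parts) {
    stop("Antichains must share the same part universe.", call. = FALSE)
  }
  all(vapply(b$members, function(bm) {
    any(vapply(a$members, function(am) all(am %in% bm), TRUE))
  }, TRUE))
}

#' Construct a product-lattice node
#'
#' A node of the double-redundancy lattice is an ordered pair of antichains,
#' one for the past and one for the future of the process.
#'
#' @param past,future `phiid_antichain` objects over the same part universe.
#' @return An object of class `phiid_node`.
#' @export
product_node <- function(past, future) {
  stopifnot(inherits(past, "phiid_antichain"), inherits(future, "phiid_antichain"))
  if (past$n_parts != future$n_parts) {
    stop("Past and future antichains must share the same part universe.",
         call. = FALSE)
  }
  structure(list(past = past, future = future, n_parts = past$n_parts),
            class = "phiid_node")
}

#' Partial order on the product lattice
#'
#' `p` precedes `q` iff `p$past` precedes `q$past` and `p$future` precedes
#' `q$future`, componentwise under [antichain_below()].
#'
#' @param p,q `phiid_node` objects.
#' @return Logical scalar.
#' @export
product_below <- function(p, q) {
  stopifnot(inherits(p, "phiid_node"), inherits(q, "phiid_node"))
  antichain_below(p$past, q$past) && antichain_below(p$future, q$future)
}

# Token naming for the bipartite lattice: the antichain {1}{2} carries the
# redundancy atom, {1}/{2} the unique atoms, {12} the synergy atom.
antichain_token <- function(a) {
  if (a$n_parts != 2L) return(format(a))
  key <- antichain_key(a)
  switch(key,
         "1:11" = "un1",
         "1:12" = "un2",
         "1:212" = "syn",
         "2:11,12" = "red",
         format(a))
}

#' Canonical label of a product-lattice node
#'
#' For bipartite systems labels follow the grammar `<past>-><future>` with
#' tokens `red`, `un1`, `un2`, `syn` (e.g. `"syn->un1"`). For other part
#' counts a generic set notation is used.
#'
#' @param node A `phiid_node`.
#' @return Character scalar.
#' @export
node_label <- function(node) {
  stopifnot(inherits(node, "phiid_node"))
  paste0(antichain_token(node$past), "->", antichain_token(node$future))
}

#' @export
format.phiid_node <- function(x, ...) node_label(x)

#' @export
print.phiid_node <- function(x, ...) {
  cat("<product node> ", node_label(x), "\n", sep = "")
  invisible(x)
}

#' Build the product (double-redundancy) lattice
#'
#' Forms the Cartesian product of the redundancy lattice with itself and
#' precomputes the order relation, strict down-sets and a bottom-up
#' (topological) traversal order. For a bipartite system the lattice has
#' exactly 16 nodes, with bottom `red->red` and top `syn->syn`; nodes are
#' enumerated past-outer / future-inner in the order `red`, `un1`, `un2`,
#' `syn`.
#'
#' @inheritParams antichain
#' @return An object of class `phiid_lattice` with elements `nodes` (list of
#'   [product_node()]s), `labels`, `leq` (full order-relation matrix),
#'   `strict_down` (list of strictly-lower node indices) and `topo`
#'   (bottom-up traversal order).
#' @examples
#' lat <- product_lattice(2)
#' length(lat$nodes)  # 16
#' @export
product_lattice <- function(n_parts) {
  acs <- antichains(n_parts)
  if (n_parts == 2) {
    tokens <- vapply(acs, antichain_token, "")
    acs <- acs[match(c("red", "un1", "un2", "syn"), tokens)]
  }
  k <- length(acs)
  nodes <- vector("list", k * k)
  idx <- 1L
  for (i in seq_len(k)) {        # past outer
    for (j in seq_len(k)) {      # future inner
      nodes[[idx]] <- product_node(acs[[i]], acs[[j]])
      idx <- idx + 1L
    }
  }
  labels <- vapply(nodes, node_label, "")
  n <- length(nodes)
  ac_leq <- outer(seq_len(k), seq_len(k),
                  Vectorize(function(i, j) antichain_below(acs[[i]], acs[[j]])))
  leq <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  for (p in seq_len(n)) {
    pi <- (p - 1L) %/% k + 1L; pj <- (p - 1L) %% k + 1L
    for (q in seq_len(n)) {
      qi <- (q - 1L) %/% k + 1L; qj <- (q - 1L) %% k + 1L
      leq[p, q] <- ac_leq[pi, qi] && ac_leq[pj, qj]
    }
  }
  strict_down <- lapply(seq_len(n), function(q) {
    setdiff(which(leq[, q]), q)
  })
  ord <- order(lengths(strict_down), labels)
  structure(list(n_parts = as.integer(n_parts), nodes = nodes, labels = labels,
                 leq = leq, strict_down = strict_down, topo = ord),
            class = "phiid_lattice")
}

#' @export
print.phiid_lattice <- function(x, ...) {
  cat("<product lattice> ", length(x$nodes), " nodes over ", x$n_parts,
      " parts\n", sep = "")
  invisible(x)
}

#' Moebius inversion: redundancies to atoms
#'
#' Given the redundancy value at every node of the product lattice, recovers
#' the information atoms by bottom-up recursion: each atom is the node's
#' redundancy minus the sum of all atoms strictly below it. The inverse
#' operation is [sum_downsets()]; the two compose to the identity on any
#' real-valued table.
#'
#' @param lattice A [product_lattice()].
#' @param redundancies Named numeric vector (bits), one value per node label.
#' @return Named numeric vector of atoms, in lattice node order.
#' @export
moebius_atoms <- function(lattice, redundancies) {
  stopifnot(inherits(lattice, "phiid_lattice"))
  missing_nodes <- setdiff(lattice$labels, names(redundancies))
  if (length(missing_nodes) > 0) {
    stop("Redundancy value missing for node(s): ",
         paste(missing_nodes, collapse = ", "), call. = FALSE)
  }
  red <- redundancies[lattice$labels]
  atoms <- stats::setNames(numeric(length(red)), lattice$labels)
  for (i in lattice$topo) {
    below <- lattice$strict_down[[i]]
    atoms[i] <- red[i] - sum(atoms[below])
  }
  atoms
}

#' Down-set summation: atoms to redundancies
#'
#' Sums atoms over the non-strict down-set of every node, reconstructing the
#' redundancy table from which [moebius_atoms()] was computed.
#'
#' @inheritParams moebius_atoms
#' @param atoms Named numeric vector of atoms, one per node label.
#' @return Named numeric vector of redundancies.
#' @export
sum_downsets <- function(lattice, atoms) {
  stopifnot(inherits(lattice, "phiid_lattice"))
  missing_nodes <- setdiff(lattice$labels, names(atoms))
  if (length(missing_nodes) > 0) {
    stop("Atom value missing for node(s): ",
         paste(missing_nodes, collapse = ", "), call. = FALSE)
  }
  a <- atoms[lattice$labels]
  vapply(seq_along(lattice$labels), function(i) {
    sum(a[lattice$leq[, i]])
  }, 0) |> stats::setNames(lattice$labels)
}

# Cached bipartite lattice (built once per session).
the <- new.env(parent = emptyenv())

bipartite_lattice <- function() {
  if (is.null(the$lat2)) the$lat2 <- product_lattice(2)
  the$lat2
}

#' The sixteen atom labels of the bipartite lattice
#'
#' @return Character vector of the 16 canonical node labels, past-outer in
#'   the order `red`, `un1`, `un2`, `syn`.
#' @export
phiid_atom_labels <- function() bipartite_lattice()$labels
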