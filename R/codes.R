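# Composite-subgraph code catalogue.
#
# A three-node composite subgraph is a triangle with one edge per node pair,
# each edge carrying a layer letter and, for directed layers, an
# orientation. The subgraph is written as a three-letter code over the edge
# slots (1-2), (1-3), (2-3); a lowercase letter marks a directed edge that
# runs against the slot order (higher-index node to lower-index node).
# Codes related by a permutation of the three nodes describe the same
# subgraph (PPC, PCP and CPP collapse); the canonical representative is the
# lexicographically smallest code over all six permutations.

# slot index of the unordered pair {i, j}, i != j, in 1..3
PAIR_INDEX <- matrix(c(NA, 1L, 2L, 1L, NA, 3L, 2L, 3L, NA), nrow = 3L)
PAIR_NODES <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
PERMS3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

# letters: length-3 character (per slot); dirs: -1 reversed, 0 undirected,
# +1 along slot order. Returns the canonical code and the permutation (old
# slot node -> new label) that achieves it.
canonical_motif <- function(letters, dirs) {
  best <- NULL
  best_perm <- NULL
  for (perm in PERMS3) {
    new_letters <- character(3L)
    new_dirs <- integer(3L)
    for (s in 1:3) {
      ij <- PAIR_NODES[[s]]
      ni <- perm[ij[1L]]
      nj <- perm[ij[2L]]
      slot <- PAIR_INDEX[ni, nj]
      new_letters[slot] <- letters[s]
      if (dirs[s] == 0L) {
        new_dirs[slot] <- 0L
      } else {
        # oriented from a to b in old labels
        from <- if (dirs[s] == 1L) ni else nj
        to <- if (dirs[s] == 1L) nj else ni
        new_dirs[slot] <- if (from < to) 1L else -1L
      }
    }
    code <- motif_code(new_letters, new_dirs)
    if (is.null(best) || lt_c(code, best)) {
      best <- code
      best_perm <- perm
    }
  }
  list(code = best, perm = best_perm)
}

motif_code <- function(letters, dirs) {
  chars <- ifelse(dirs == -1L, tolower(letters), letters)
  paste(chars, collapse = "")
}

# Parse a code back into per-slot letters and directions, given the set of
# directed letters.
parse_code <- function(code, directed_letters) {
  chars <- strsplit(code, "")[[1L]]
  upper <- toupper(chars)
  dirs <- integer(3L)
  for (s in 1:3) {
    if (upper[s] %in% directed_letters) {
      dirs[s] <- if (chars[s] == upper[s]) 1L else -1L
    } else {
      dirs[s] <- 0L
    }
  }
  list(letters = upper, dirs = dirs)
}

# Topological class of a triangle motif from its per-slot directions.
classify_motif <- function(dirs) {
  n_undir <- sum(dirs == 0L)
  if (n_undir == 3L) return("COM")
  if (n_undir == 2L) return("FB2U")
  if (n_undir == 0L) {
    # directed triangle: out-degree per node
    outdeg <- integer(3L)
    for (s in 1:3) {
      ij <- PAIR_NODES[[s]]
      from <- if (dirs[s] == 1L) ij[1L] else ij[2L]
      outdeg[from] <- outdeg[from] + 1L
    }
    return(if (all(outdeg == 1L)) "CIR" else "FFL")
  }
  # exactly one undirected edge
  u_slot <- which(dirs == 0L)
  uv <- PAIR_NODES[[u_slot]]
  z <- setdiff(1:3, uv)
  heads <- integer(0)
  tails <- integer(0)
  for (s in setdiff(1:3, u_slot)) {
    ij <- PAIR_NODES[[s]]
    from <- if (dirs[s] == 1L) ij[1L] else ij[2L]
    to <- if (dirs[s] == 1L) ij[2L] else ij[1L]
    heads <- c(heads, to)
    tails <- c(tails, from)
  }
  if (all(heads == z)) return("COP")   # both directed edges converge on z
  if (all(tails == z)) return("COR")   # z regulates both ends of the undirected edge
  "FBU"                                # directed cascade closed by an undirected edge
}

#' Generate the non-redundant catalogue of three-node subgraph codes
#'
#' Enumerates every assignment of layer letters (and, for directed layers,
#' orientations) to the three edges of a triangle, collapses assignments
#' related by a node permutation, and classifies each canonical code into
#' one of the seven three-node topological types (COM, COP, COR, FFL, CIR,
#' FBU, FB2U). Users may subtract unwanted codes from the result before
#' enumeration.
#'
#' @param directed_letters Character vector of directed layer letters.
#' @param undirected_letters Character vector of undirected layer letters.
#' @return A tibble with columns `code` and `topo_type`, sorted by code.
#' @examples
#' subgraph_codes(character(), "P")          # the all-P triangle (COM)
#' subgraph_codes("R", character())          # cyclic (CIR) + transitive (FFL)
#' @export
subgraph_codes <- function(directed_letters, undirected_letters) {
  directed_letters <- unique(as.character(directed_letters))
  undirected_letters <- unique(as.character(undirected_letters))
  if (length(intersect(directed_letters, undirected_letters))) {
    stop("directed and undirected letter sets overlap", call. = FALSE)
  }
  if (length(directed_letters) + length(undirected_letters) == 0L) {
    stop("at least one layer letter is required", call. = FALSE)
  }
  opts <- c(lapply(directed_letters, function(l) list(list(l, 1L), list(l, -1L))),
            lapply(undirected_letters, function(l) list(list(l, 0L))))
  opts <- unlist(opts, recursive = FALSE)
  n <- length(opts)
  seen <- new.env(parent = emptyenv())
  out_code <- character()
  out_type <- character()
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    letters <- c(opts[[i]][[1L]], opts[[j]][[1L]], opts[[k]][[1L]])
    dirs <- c(opts[[i]][[2L]], opts[[j]][[2L]], opts[[k]][[2L]])
    code <- canonical_motif(letters, dirs)$code
    if (is.null(seen[[code]])) {
      seen[[code]] <- TRUE
      out_code <- c(out_code, code)
      parsed <- parse_code(code, directed_letters)
      out_type <- c(out_type, classify_motif(parsed$dirs))
    }
  }
  ord <- order(out_code, method = "radix")
  tibble::tibble(code = out_code[ord], topo_type = out_type[ord])
}

#' Catalogue of codes for a composite network
#'
#' Convenience wrapper deriving the directed/undirected letter sets from a
#' network's layer table.
#'
#' @param network A `composite_network`.
#' @return A tibble of canonical codes with topological types.
#' @export
network_codes <- function(network) {
  subgraph_codes(network$layers$letter[network$layers$directed],
                 network$layers$letter[!network$layers$directed])
}
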