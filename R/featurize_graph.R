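# Molecular-graph featurization: an amino-acid sequence becomes the
# heavy-atom graph of the corresponding linear peptide, built residue by
# residue from structural templates (backbone N, CA, C, O plus the side
# chain), with one water removed per peptide bond and a terminal carboxyl
# oxygen (OXT) on the last residue. Hydrogens are implicit; no 3D
# coordinates are used anywhere.

# Side-chain templates: atom name -> element, bonds as (from, to, order).
# Backbone atoms N, CA, C, O and their bonds are added for every residue;
# side chains attach at CA (proline additionally closes a ring to N).
pb_sidechains <- local({
  b <- function(...) {
    m <- matrix(c(...), ncol = 3L, byrow = TRUE)
    data.frame(from = m[, 1L], to = m[, 2L], order = m[, 3L],
               stringsAsFactors = FALSE)
  }
  ring6 <- function(a1, a2, a3, a4, a5, a6) {
    b(a1, a2, "aromatic", a2, a3, "aromatic", a3, a4, "aromatic",
      a4, a5, "aromatic", a5, a6, "aromatic", a6, a1, "aromatic")
  }
  list(
    G = list(atoms = c(), bonds = NULL, smiles = "NCC(=O)"),
    A = list(atoms = c(CB = "C"), bonds = b("CA", "CB", "single"),
             smiles = "NC(C)C(=O)"),
    V = list(atoms = c(CB = "C", CG1 = "C", CG2 = "C"),
             bonds = b("CA", "CB", "single", "CB", "CG1", "single",
                       "CB", "CG2", "single"),
             smiles = "NC(C(C)C)C(=O)"),
    L = list(atoms = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C"),
             bonds = b("CA", "CB", "single", "CB", "CG", "single",
                       "CG", "CD1", "single", "CG", "CD2", "single"),
             smiles = "NC(CC(C)C)C(=O)"),
    I = list(atoms = c(CB = "C", CG1 = "C", CG2 = "C", CD1 = "C"),
             bonds = b("CA", "CB", "single", "CB", "CG1", "single",
                       "CB", "CG2", "single", "CG1", "CD1", "single"),
             smiles = "NC(C(C)CC)C(=O)"),
    P = list(atoms = c(CB = "C", CG = "C", CD = "C"),
             bonds = b("CA", "CB", "single", "CB", "CG", "single",
                       "CG", "CD", "single", "CD", "N", "single"),
             smiles = "N1C(CCC1)C(=O)"),
    F = list(atoms = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C",
                       CE1 = "C", CE2 = "C", CZ = "C"),
             bonds = rbind(b("CA", "CB", "single", "CB", "CG", "single"),
                           ring6("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
             smiles = "NC(Cc1ccccc1)C(=O)"),
    Y = list(atoms = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C",
                       CE1 = "C", CE2 = "C", CZ = "C", OH = "O"),
             bonds = rbind(b("CA", "CB", "single", "CB", "CG", "single",
                             "CZ", "OH", "single"),
                           ring6("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
             smiles = "NC(Cc1ccc(O)cc1)C(=O)"),
    W = list(atoms = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C", NE1 = "N",
                       CE2 = "C", CE3 = "C", CZ2 = "C", CZ3 = "C", CH2 = "C"),
             bonds = rbind(
               b("CA", "CB", "single", "CB", "CG", "single",
                 "CG", "CD1", "aromatic", "CD1", "NE1", "aromatic",
                 "NE1", "CE2", "aromatic", "CE2", "CD2", "aromatic",
                 "CD2", "CG", "aromatic"),
               b("CD2", "CE3", "aromatic", "CE3", "CZ3", "aromatic",
                 "CZ3", "CH2", "aromatic", "CH2", "CZ2", "aromatic",
                 "CZ2", "CE2", "aromatic")),
             smiles = "NC(Cc1c[nH]c2ccccc12)C(=O)"),
    S = list(atoms = c(CB = "C", OG = "O"),
             bonds = b("CA", "CB", "single", "CB", "OG", "single"),
             smiles = "NC(CO)C(=O)"),
    T = list(atoms = c(CB = "C", OG1 = "O", CG2 = "C"),
             bonds = b("CA", "CB", "single", "CB", "OG1", "single",
                       "CB", "CG2", "single"),
             smiles = "NC(C(O)C)C(=O)"),
    C = list(atoms = c(CB = "C", SG = "S"),
             bonds = b("CA", "CB", "single", "CB", "SG", "single"),
             smiles = "NC(CS)C(=O)"),
    M = list(atoms = c(CB = "C", CG = "C", SD = "S", CE = "C"),
             bonds = b("CA", "CB", "single", "CB", "CG", "single",
                       "CG", "SD", "single", "SD", "CE", "single"),
             smiles = "NC(CCSC)C(=O)"),
    N = list(atoms = c(CB = "C", CG = "C", OD1 = "O", ND2 = "N"),
             bonds = b("CA", "CB", "single", "CB", "CG", "single",
                       "CG", "OD1", "double", "CG", "ND2", "single"),
             smiles = "NC(CC(=O)N)C(=O)"),
    Q = list(atoms = c(CB = "C", CG = "C", CD = "C", OE1 = "O", NE2 = "N"),
             bonds = b("CA", "CB", "single", "CB", "CG", "single",
                       "CG", "CD", "single", "CD", "OE1", "double",
                       "CD", "NE2", "single"),
             smiles = "NC(CCC(=O)N)C(=O)"),
    D = list(atoms = c(CB = "C", CG = "C", OD1 = "O", OD2 = "O"),
             bonds = b("CA", "CB", "single", "CB", "CG", "single",
                       "CG", "OD1", "double", "CG", "OD2", "single"),
             smiles = "NC(CC(=O)O)C(=O)"),
    E = list(atoms = c(CB = "C", CG = "C", CD = "C", OE1 = "O", OE2 = "O"),
             bonds = b("CA", "CB", "single", "CB", "CG", "single",
                       "CG", "CD", "single", "CD", "OE1", "double",
                       "CD", "OE2", "single"),
             smiles = "NC(CCC(=O)O)C(=O)"),
    K = list(atoms = c(CB = "C", CG = "C", CD = "C", CE = "C", NZ = "N"),
             bonds = b("CA", "CB", "single", "CB", "CG", "single",
                       "CG", "CD", "single", "CD", "CE", "single",
                       "CE", "NZ", "single"),
             smiles = "NC(CCCCN)C(=O)"),
    R = list(atoms = c(CB = "C", CG = "C", CD = "C", NE = "N", CZ = "C",
                       NH1 = "N", NH2 = "N"),
             bonds = b("CA", "CB", "single", "CB", "CG", "single",
                       "CG", "CD", "single", "CD", "NE", "single",
                       "NE", "CZ", "single", "CZ", "NH1", "double",
                       "CZ", "NH2", "single"),
             smiles = "NC(CCCNC(=N)N)C(=O)"),
    H = list(atoms = c(CB = "C", CG = "C", ND1 = "N", CD2 = "C",
                       CE1 = "C", NE2 = "N"),
             bonds = b("CA", "CB", "single", "CB", "CG", "single",
                       "CG", "ND1", "aromatic", "ND1", "CE1", "aromatic",
                       "CE1", "NE2", "aromatic", "NE2", "CD2", "aromatic",
                       "CD2", "CG", "aromatic"),
             smiles = "NC(Cc1c[nH]cn1)C(=O)")
  )
})

#' Build the molecular graph of a linear peptide
#'
#' Condenses the sequence N-to-C into one molecule (one water removed per
#' peptide bond), keeping heavy atoms only. The undirected edge list has no
#' self-loops; GCN-style self-loops are added inside the models.
#'
#' @param sequence String over the 20 canonical amino acids.
#' @return A `pb_graph`: `n_atoms`, `elements`, `atom_names`, `bonds`
#'   (data.frame `from`, `to`, `order` with 1-based atom indices), and
#'   `residue_of` (which residue each atom belongs to).
#' @examples
#' g <- sequence_to_peptide_graph("G")  # 5 heavy atoms, 4 bonds
#' @export
sequence_to_peptide_graph <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1L]]
  if (length(ch) == 0L) pb_stop("pb_empty_sequence", "empty sequence")
  bad <- setdiff(ch, names(pb_sidechains))
  if (length(bad) > 0L) {
    pb_stop("pb_unsupported_residue", sprintf(
      "unsupported residue(s) for graph construction: %s",
      paste(unique(bad), collapse = ", ")))
  }
  elements <- character(0)
  names_ <- character(0)
  resid <- integer(0)
  from <- integer(0); to <- integer(0); ord <- character(0)
  prev_C <- NA_integer_
  for (i in seq_along(ch)) {
    tpl <- pb_sidechains[[ch[i]]]
    local_atoms <- c(c(N = "N", CA = "C", C = "C", O = "O"), tpl$atoms)
    offset <- length(elements)
    idx <- stats::setNames(offset + seq_along(local_atoms), names(local_atoms))
    elements <- c(elements, unname(local_atoms))
    names_ <- c(names_, names(local_atoms))
    resid <- c(resid, rep.int(i, length(local_atoms)))
    bb <- data.frame(from = c("N", "CA", "C"), to = c("CA", "C", "O"),
                     order = c("single", "single", "double"),
                     stringsAsFactors = FALSE)
    all_bonds <- rbind(bb, tpl$bonds)
    from <- c(from, idx[all_bonds$from])
    to <- c(to, idx[all_bonds$to])
    ord <- c(ord, all_bonds$order)
    if (!is.na(prev_C)) {  # peptide bond C(i-1)-N(i)
      from <- c(from, prev_C); to <- c(to, idx[["N"]])
      ord <- c(ord, "single")
    }
    prev_C <- idx[["C"]]
  }
  # terminal carboxyl oxygen
  elements <- c(elements, "O")
  names_ <- c(names_, "OXT")
  resid <- c(resid, length(ch))
  from <- c(from, prev_C); to <- c(to, length(elements))
  ord <- c(ord, "single")
  structure(list(n_atoms = length(elements), elements = elements,
                 atom_names = names_, residue_of = resid,
                 bonds = data.frame(from = unname(from), to = unname(to),
                                    order = ord, stringsAsFactors = FALSE)),
            class = "pb_graph")
}

#' @export
print.pb_graph <- function(x, ...) {
  cat(sprintf("<peptide graph> %d heavy atoms, %d bonds\n", x$n_atoms,
              nrow(x$bonds)))
  invisible(x)
}

#' Atom (node) features
#'
#' Each atom is encoded as a one-hot element indicator over the palette
#' concatenated with its scaled degree (degree / 4), giving
#' `length(palette) + 1` features per node.
#'
#' @param graph A `pb_graph`.
#' @param element_palette Character vector of allowed elements.
#' @return Numeric matrix, `n_atoms` x `(length(palette) + 1)`.
#' @export
featurize_atoms <- function(graph, element_palette = c("C", "N", "O", "S")) {
  el <- match(graph$elements, element_palette)
  if (anyNA(el)) {
    pb_stop("pb_unknown_element", sprintf(
      "element(s) outside the palette: %s",
      paste(unique(graph$elements[is.na(el)]), collapse = ", ")))
  }
  deg <- tabulate(c(graph$bonds$from, graph$bonds$to), nbins = graph$n_atoms)
  H <- matrix(0, graph$n_atoms, length(element_palette) + 1L)
  H[cbind(seq_len(graph$n_atoms), el)] <- 1
  H[, length(element_palette) + 1L] <- deg / 4
  H
}

#' Bond (edge) features
#'
#' One-hot bond order over {single, double, aromatic} for every directed
#' copy of each bond; the two directions of a bond carry identical features.
#'
#' @param graph A `pb_graph`.
#' @return List with `src`, `dst` (directed edge endpoints, both directions
#'   of every bond) and `features` (n_directed_edges x 3 matrix).
#' @export
featurize_bonds <- function(graph) {
  orders <- c("single", "double", "aromatic")
  o <- match(graph$bonds$order, orders)
  stopifnot(!anyNA(o))
  src <- c(graph$bonds$from, graph$bonds$to)
  dst <- c(graph$bonds$to, graph$bonds$from)
  E <- matrix(0, length(src), 3L)
  E[cbind(seq_along(src), c(o, o))] <- 1
  colnames(E) <- orders
  list(src = src, dst = dst, features = E)
}

#' Export a peptide as a SMILES string
#'
#' Debugging aid: renders the same linear-peptide condensation used by
#' [sequence_to_peptide_graph()] as SMILES (no stereochemistry).
#'
#' @param sequence String over the 20 canonical amino acids.
#' @return SMILES string of the peptide.
#' @export
peptide_smiles <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(ch, names(pb_sidechains))
  if (length(bad) > 0L) {
    pb_stop("pb_unsupported_residue", sprintf(
      "unsupported residue(s): %s", paste(unique(bad), collapse = ", ")))
  }
  paste0(paste(vapply(ch, function(a) pb_sidechains[[a]]$smiles, ""),
               collapse = ""), "O")
}

#' Write a graph as an edge-list text file
#'
#' @param graph A `pb_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_edgelist <- function(graph, path) {
  df <- data.frame(from = graph$bonds$from, to = graph$bonds$to,
                   order = graph$bonds$order,
                   from_element = graph$elements[graph$bonds$from],
                   to_element = graph$elements[graph$bonds$to])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Batch a list of pb_graphs into block-diagonal form for the graph models:
# node features stacked, directed edges re-indexed, per-node graph ids.
batch_graphs <- function(graphs, element_palette = c("C", "N", "O", "S")) {
  if (length(graphs) == 0L) pb_stop("pb_empty_batch", "no graphs to batch")
  offs <- cumsum(c(0L, vapply(graphs, function(g) g$n_atoms, integer(1L))))
  H <- do.call(rbind, lapply(graphs, featurize_atoms, element_palette = element_palette))
  src <- integer(0); dst <- integer(0); E <- NULL
  node_graph <- integer(0)
  for (i in seq_along(graphs)) {
    eb <- featurize_bonds(graphs[[i]])
    src <- c(src, eb$src + offs[i])
    dst <- c(dst, eb$dst + offs[i])
    E <- rbind(E, eb$features)
    node_graph <- c(node_graph, rep.int(i, graphs[[i]]$n_atoms))
  }
  list(H = H, src = src, dst = dst, edge_features = E,
       node_graph = node_graph, n_graphs = length(graphs),
       n_nodes = nrow(H), graphs = graphs)
}
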