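#' Write an LV mesh in Gmsh MSH 2.2 ASCII format
#'
#' Quadratic tetrahedra (type 11) and labeled quadratic boundary triangles
#' (type 9) with physical surface names "endo", "epi", "base" and volume
#' "wall". Parametric coordinates are not persisted; a mesh read back can be
#' re-fibered via the harmonic transmural coordinate.
#'
#' @param mesh an `lv_mesh`.
#' @param path output file path.
#' @export
write_lv_mesh <- function(mesh, path) {
  # internal -> gmsh TET10 midside permutation: gmsh edge order is
  # (1,2),(2,3),(3,1),(1,4),(3,4),(2,4)
  perm <- c(1:4, 5, 6, 7, 8, 10, 9)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  wl("$PhysicalNames", "4",
     "2 1 \"endo\"", "2 2 \"epi\"", "2 3 \"base\"", "3 4 \"wall\"",
     "$EndPhysicalNames")
  n <- nrow(mesh$nodes)
  wl("$Nodes", as.character(n))
  wl(sprintf("%d %.16g %.16g %.16g", seq_len(n), mesh$nodes[, 1],
             mesh$nodes[, 2], mesh$nodes[, 3]))
  wl("$EndNodes")
  surf <- list(endo = 1L, epi = 2L, base = 3L)
  ne_surf <- sum(vapply(mesh$faces, nrow, 1L))
  ne <- nrow(mesh$elems)
  wl("$Elements", as.character(ne_surf + ne))
  id <- 0L
  lines <- character(0)
  for (nm in names(surf)) {
    f <- mesh$faces[[nm]]
    if (nrow(f) == 0) next
    tag <- surf[[nm]]
    lines <- c(lines, sprintf("%d 9 2 %d %d %s", id + seq_len(nrow(f)), tag,
                              tag, apply(f, 1, paste, collapse = " ")))
    id <- id + nrow(f)
  }
  ep <- mesh$elems[, perm, drop = FALSE]
  lines <- c(lines, sprintf("%d 11 2 4 4 %s", id + seq_len(ne),
                            apply(ep, 1, paste, collapse = " ")))
  wl(lines, "$EndElements")
  invisible(path)
}

#' Read an LV mesh written by [write_lv_mesh()]
#'
#' @param path Gmsh MSH 2.2 ASCII file with physical surfaces
#'   endo/epi/base and a TET10 volume.
#' @return an `lv_mesh` (without parametric coordinates or spec).
#' @export
read_lv_mesh <- function(path) {
  txt <- readLines(path)
  sec <- function(name) {
    i0 <- which(txt == paste0("$", name)) + 1L
    i1 <- which(txt == paste0("$End", name)) - 1L
    if (length(i0) != 1 || length(i1) != 1) stop_lv("malformed mesh file: missing $%s", name)
    txt[i0:i1]
  }
  nd <- sec("Nodes")
  nn <- as.integer(nd[1])
  nm <- matrix(scan(text = nd[-1], quiet = TRUE), ncol = 4, byrow = TRUE)
  nodes <- nm[order(nm[, 1]), 2:4, drop = FALSE]
  el <- sec("Elements")
  faces <- list(endo = list(), epi = list(), base = list())
  tag_names <- c("endo", "epi", "base")
  elems <- list()
  perm_back <- c(1:4, 5, 6, 7, 8, 10, 9)  # self-inverse swap of last two
  for (ln in el[-1]) {
    v <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])
    type <- v[2]; ntags <- v[3]
    phys <- v[4]
    conn <- v[(4 + ntags):length(v)]
    if (type == 9) {
      faces[[tag_names[phys]]][[length(faces[[tag_names[phys]]]) + 1L]] <- conn
    } else if (type == 11) {
      elems[[length(elems) + 1L]] <- conn[perm_back]
    }
  }
  elems <- do.call(rbind, elems)
  storage.mode(elems) <- "integer"
  faces <- lapply(faces, function(l) {
    if (length(l) == 0) matrix(integer(0), 0, 6) else {
      m <- do.call(rbind, l); storage.mode(m) <- "integer"; m
    }
  })
  structure(list(nodes = nodes, elems = elems, faces = faces,
                 param = NULL, spec = NULL),
            class = "lv_mesh")
}
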