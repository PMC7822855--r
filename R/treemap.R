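# Clonal tree-maps: a V -> V-J -> V-J-CDR3 hierarchy laid out as nested
# rectangles with area proportional to copy frequency. Siblings are placed
# by a squarified tiling, ordered largest at the bottom right to smallest
# at the top left; leaves get seeded random colors and rounded corners.

#' Build the V -> V-J -> V-J-CDR3 hierarchy
#'
#' Copy-weighted frequencies; the root has frequency 1 and one child per
#' distinct V gene, each V child one child per V-J combination, each V-J
#' child one leaf per CDR3 nucleotide sequence.
#'
#' @param clonotypes data.frame from [build_clonotypes()] with V and J
#'   calls.
#' @return the root `treemap_node` (list: `level`, `label`, `frequency`,
#'   `children`).
#' @export
build_hierarchy <- function(clonotypes) {
  if (nrow(clonotypes) == 0) stopf("empty repertoire")
  if (any(is.na(clonotypes$v_gene)) || any(is.na(clonotypes$j_gene)))
    stopf("clonotypes must carry V and J calls")
  total <- sum(clonotypes$total_copies)
  node <- function(level, label, freq, children = list())
    list(level = level, label = label, frequency = freq, children = children)

  vs <- split(clonotypes, clonotypes$v_gene)
  vnodes <- lapply(names(vs), function(v) {
    dv <- vs[[v]]
    js <- split(dv, dv$j_gene)
    jnodes <- lapply(names(js), function(j) {
      dj <- js[[j]]
      leaves <- lapply(seq_len(nrow(dj)), function(i)
        node("VJCDR3", dj$cdr3_nt[i], dj$total_copies[i] / total))
      node("VJ", paste(v, j, sep = "-"), sum(dj$total_copies) / total, leaves)
    })
    node("V", v, sum(dv$total_copies) / total, jnodes)
  })
  node("root", "repertoire", 1, vnodes)
}

worst_aspect <- function(row, side) {
  s <- sum(row)
  max(vapply(row, function(a)
    max(side^2 * a / s^2, s^2 / (side^2 * a)), numeric(1)))
}

# squarified tiling of `areas` (already descending) into rect (x, y, w, h);
# first item lands top-left; returns rects in input order
squarify <- function(areas, x, y, w, h) {
  rects <- vector("list", length(areas))
  i <- 1L; n <- length(areas)
  while (i <= n) {
    side <- min(w, h)
    j <- i
    row <- areas[i]
    while (j < n &&
           worst_aspect(areas[i:(j + 1L)], side) <=
           worst_aspect(row, side) + 1e-12) {
      j <- j + 1L
      row <- areas[i:j]
    }
    thick <- sum(row) / side
    off <- 0
    if (w >= h) {  # vertical strip on the left, items top to bottom
      for (k in i:j) {
        len <- areas[k] / thick
        rects[[k]] <- c(x, y + off, thick, len)
        off <- off + len
      }
      x <- x + thick; w <- w - thick
    } else {       # horizontal strip on top, items left to right
      for (k in i:j) {
        len <- areas[k] / thick
        rects[[k]] <- c(x + off, y, len, thick)
        off <- off + len
      }
      y <- y + thick; h <- h - thick
    }
    i <- j + 1L
  }
  rects
}

# point-reflect a rect about the center of (x0, y0, w0, h0); a reflected
# tiling is still a tiling, with the first-placed (largest) rect moved from
# the top left to the bottom right
reflect_rect <- function(r, x0, y0, w0, h0) {
  c(2 * x0 + w0 - r[1] - r[3], 2 * y0 + h0 - r[2] - r[4], r[3], r[4])
}

layout_children <- function(node) {
  if (!length(node$children)) return(node)
  ord <- order(-vapply(node$children, `[[`, numeric(1), "frequency"))
  children <- node$children[ord]
  x0 <- node$rect[1]; y0 <- node$rect[2]
  w0 <- node$rect[3]; h0 <- node$rect[4]
  areas <- vapply(children, `[[`, numeric(1), "frequency") /
    node$frequency * (w0 * h0)
  rects <- squarify(areas, x0, y0, w0, h0)
  for (k in seq_along(children)) {
    children[[k]]$rect <- reflect_rect(rects[[k]], x0, y0, w0, h0)
    children[[k]] <- layout_children(children[[k]])
  }
  node$children <- children
  node
}

assign_colors <- function(node, env) {
  if (!length(node$children)) {
    hue <- runif(1)
    tries <- 0L
    while (!is.na(env$prev) && abs(hue - env$prev) < 0.08 && tries < 10L) {
      hue <- runif(1); tries <- tries + 1L
    }
    env$prev <- hue
    node$color <- grDevices::hsv(hue, 0.55, 0.85)
    return(node)
  }
  node$children <- lapply(node$children, assign_colors, env = env)
  node
}

#' Lay out a tree-map hierarchy
#'
#' Recursive squarified tiling that fills each parent rectangle exactly;
#' sibling rectangles are ordered from largest at the bottom right to
#' smallest at the top left. Leaf colors are drawn from a seeded uniform
#' hue with fixed saturation/value, re-drawing near-duplicate consecutive
#' hues. Deterministic given `seed`.
#'
#' @param root the hierarchy from [build_hierarchy()].
#' @param width,height canvas size in user units.
#' @param seed integer seed for the color draws.
#' @return the hierarchy with a `rect = c(x, y, w, h)` on every node and a
#'   `color` on every leaf.
#' @export
layout_treemap <- function(root, width = 600, height = 400, seed = 1) {
  stopifnot(width > 0, height > 0)
  root$rect <- c(0, 0, width, height)
  root <- layout_children(root)
  with_local_seed(seed, {
    env <- new.env(); env$prev <- NA_real_
    root <- assign_colors(root, env)
  })
  root
}

collect_nodes <- function(node, level) {
  out <- if (node$level %in% level) list(node) else list()
  for (ch in node$children) out <- c(out, collect_nodes(ch, level))
  out
}

#' Render a laid-out tree-map to SVG
#'
#' One rounded rectangle per leaf (CDR3), plus V- and V-J-level border
#' rectangles. Output is plain SVG 1.1 text and is byte-identical for
#' identical input.
#'
#' @param root a laid-out hierarchy from [layout_treemap()].
#' @param path output SVG path.
#' @param corner_radius leaf corner radius in canvas units (0 = square).
#' @return invisibly, `path`.
#' @export
render_svg <- function(root, path, corner_radius = 3) {
  if (is.null(root$rect)) stopf("layout_treemap() must be applied first")
  f <- function(v) formatC(v, format = "f", digits = 4)
  w <- root$rect[3]; h <- root$rect[4]
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
                   "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">"),
            f(w), f(h), f(w), f(h)))
  for (leaf in collect_nodes(root, "VJCDR3"))
    lines <- c(lines, sprintf(
      paste0("<rect class=\"leaf\" x=\"%s\" y=\"%s\" width=\"%s\" ",
             "height=\"%s\" rx=\"%s\" ry=\"%s\" fill=\"%s\" ",
             "stroke=\"#ffffff\" stroke-width=\"0.5\"/>"),
      f(leaf$rect[1]), f(leaf$rect[2]), f(leaf$rect[3]), f(leaf$rect[4]),
      f(corner_radius), f(corner_radius), leaf$color))
  for (grp in collect_nodes(root, c("V", "VJ"))) {
    sw <- if (grp$level == "V") "2" else "1"
    lines <- c(lines, sprintf(
      paste0("<rect class=\"group\" x=\"%s\" y=\"%s\" width=\"%s\" ",
             "height=\"%s\" fill=\"none\" stroke=\"#333333\" ",
             "stroke-width=\"%s\"/>"),
      f(grp$rect[1]), f(grp$rect[2]), f(grp$rect[3]), f(grp$rect[4]), sw))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
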