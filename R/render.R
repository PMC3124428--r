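#' Figure specification
#'
#' Options for the SVG figure: canvas size, per-locus colors, the displayed
#' time window, which curve to show, and optional epoch shading. The time
#' axis runs from the present (t = 0) at the left toward the root at the
#' right; `flip_time` mirrors it.
#'
#' @param width,height canvas size in px.
#' @param colors named (by locus) or unnamed character vector of hex colors;
#'   defaults to a colorblind-safe 8-color cycle.
#' @param time_window numeric pair restricting the displayed times,
#'   default the full `[0, depth]`.
#' @param show which profile curve to draw: `"per_site"` (default) or
#'   `"net"`.
#' @param epoch_shading optional list of epochs `c(t1, t2)` drawn as shaded
#'   bands.
#' @param flip_time mirror the time axis (present at the right).
#' @return a `pi_plot_spec` list.
#' @export
plot_spec <- function(width = 800, height = 600, colors = NULL,
                      time_window = NULL, show = c("per_site", "net"),
                      epoch_shading = NULL, flip_time = FALSE) {
  show <- match.arg(show)
  if (!is.null(colors) &&
      !all(grepl("^#[0-9A-Fa-f]{6}$", colors)))
    stop("colors must be hex strings like '#0072B2'", call. = FALSE)
  if (!is.null(time_window)) {
    if (length(time_window) != 2 || diff(time_window) <= 0)
      stop("time_window must be c(t0, t1) with t1 > t0", call. = FALSE)
  }
  structure(list(width = width, height = height, colors = colors,
                 time_window = time_window, show = show,
                 epoch_shading = epoch_shading, flip_time = flip_time),
            class = "pi_plot_spec")
}

PALETTE <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442",
             "#0072B2", "#D55E00", "#CC79A7", "#999999")

MARGIN <- c(left = 60, right = 20, top = 20, bottom = 45)

fmt <- function(x) sprintf("%.4f", x)

# Shared linear time -> x mapping; the one transform used by both panels.
x_transform <- function(spec, depth) {
  win <- if (is.null(spec$time_window)) c(0, depth) else spec$time_window
  if (win[1] < 0 || win[2] > depth * (1 + 1e-9))
    stop(sprintf("time_window must lie within [0, %g]", depth), call. = FALSE)
  x0 <- MARGIN["left"]
  x1 <- spec$width - MARGIN["right"]
  if (spec$flip_time) {
    function(t) unname(x1 - (t - win[1]) / (win[2] - win[1]) * (x1 - x0))
  } else {
    function(t) unname(x0 + (t - win[1]) / (win[2] - win[1]) * (x1 - x0))
  }
}

locus_colors <- function(loci, spec) {
  if (is.null(spec$colors)) {
    cols <- rep(PALETTE, length.out = length(loci))
    names(cols) <- loci
    return(cols)
  }
  cols <- spec$colors
  if (is.null(names(cols))) {
    if (length(cols) < length(loci))
      stop(sprintf("need %d colors, got %d", length(loci), length(cols)),
           call. = FALSE)
    cols <- stats::setNames(cols[seq_along(loci)], loci)
  } else if (!all(loci %in% names(cols))) {
    stop("named colors must cover every displayed locus", call. = FALSE)
  }
  cols[loci]
}

# Deterministic tip ordering: at each node children are sorted by clade size
# (small clades first), ties broken by their alphabetically smallest tip.
ladder_order <- function(tree) {
  ntip <- ape::Ntip(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  first_tip <- character(ntip + tree$Nnode)
  sizes <- integer(ntip + tree$Nnode)
  tip_order <- integer(0)
  info <- function(node) {
    if (node <= ntip) {
      sizes[node] <<- 1L
      first_tip[node] <<- tree$tip.label[node]
      return(invisible(NULL))
    }
    for (ch in children[[as.character(node)]]) info(ch)
    kids <- children[[as.character(node)]]
    sizes[node] <<- sum(sizes[kids])
    first_tip[node] <<- min(first_tip[kids])
    invisible(NULL)
  }
  walk <- function(node) {
    if (node <= ntip) {
      tip_order <<- c(tip_order, node)
      return(invisible(NULL))
    }
    kids <- children[[as.character(node)]]
    kids <- kids[order(sizes[kids], first_tip[kids])]
    for (ch in kids) walk(ch)
    invisible(NULL)
  }
  root <- ntip + 1L
  info(root)
  walk(root)
  tip_order
}

# Rectangular chronogram fragment on the shared x-transform.
tree_fragment <- function(tree, spec, xf, y0, y1) {
  ntip <- ape::Ntip(tree)
  depth <- tree_depth(tree)
  dist_root <- ape::node.depth.edgelength(tree)
  node_time <- depth - dist_root            # tips ~0, root = depth
  tip_order <- ladder_order(tree)
  ys <- numeric(ntip + tree$Nnode)
  ys[tip_order] <- seq(y0, y1, length.out = ntip)
  # internal y = mean of children, computed in postorder
  po <- stats::reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    parent <- po[e, 1]
    kids <- tree$edge[tree$edge[, 1] == parent, 2]
    ys[parent] <- mean(ys[kids])
  }
  out <- c(sprintf('<g class="tree" fill="none" stroke="#333333" stroke-width="1.5">'))
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    out <- c(out,
      sprintf('<path d="M %s %s L %s %s L %s %s"/>',
              fmt(xf(node_time[parent])), fmt(ys[parent]),
              fmt(xf(node_time[parent])), fmt(ys[child]),
              fmt(xf(node_time[child])), fmt(ys[child])))
  }
  out <- c(out, "</g>", '<g class="tip-labels" font-family="sans-serif" font-size="11">')
  lab_dx <- if (spec$flip_time) -4 else 4
  anchor <- if (spec$flip_time) "end" else "start"
  for (i in tip_order) {
    out <- c(out, sprintf('<text class="tip" x="%s" y="%s" text-anchor="%s">%s</text>',
                          fmt(xf(node_time[i]) + lab_dx), fmt(ys[i] + 4),
                          anchor, xml_escape(tree$tip.label[i])))
  }
  c(out, "</g>")
}

profiles_fragment <- function(profile, spec, xf, y0, y1, loci, cols) {
  win <- if (is.null(spec$time_window))
    c(0, attr(profile, "depth")) else spec$time_window
  column <- if (spec$show == "per_site") "per_site" else "net"
  keep <- profile$time >= win[1] - 1e-12 & profile$time <= win[2] + 1e-12
  sub <- profile[keep, ]
  ymax <- max(sub[[column]], 1e-12)
  yf <- function(v) y1 - v / ymax * (y1 - y0)
  out <- character(0)
  for (ep in spec$epoch_shading) {
    out <- c(out, sprintf('<rect class="epoch" x="%s" y="%s" width="%s" height="%s" fill="#000000" fill-opacity="0.08"/>',
                          fmt(min(xf(ep[1]), xf(ep[2]))), fmt(y0),
                          fmt(abs(xf(ep[2]) - xf(ep[1]))), fmt(y1 - y0)))
  }
  out <- c(out, '<g class="profiles" fill="none" stroke-width="2">')
  for (lc in loci) {
    pts <- sub[sub$locus == lc, ]
    coords <- paste(fmt(xf(pts$time)), fmt(yf(pts[[column]])),
                    sep = ",", collapse = " ")
    out <- c(out, sprintf('<polyline class="locus" data-locus="%s" stroke="%s" points="%s"/>',
                          xml_escape(lc), cols[[lc]], coords))
  }
  out <- c(out, "</g>")
  # axes
  xticks <- pretty(win, n = 6)
  xticks <- xticks[xticks >= win[1] & xticks <= win[2]]
  yticks <- pretty(c(0, ymax), n = 5)
  yticks <- yticks[yticks >= 0 & yticks <= ymax]
  ax <- c(sprintf('<g class="axes" stroke="#000000" stroke-width="1" font-family="sans-serif" font-size="10">'),
          sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s"/>',
                  fmt(xf(win[1])), fmt(y1), fmt(xf(win[2])), fmt(y1)),
          sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s"/>',
                  fmt(MARGIN["left"]), fmt(y0), fmt(MARGIN["left"]), fmt(y1)))
  for (tk in xticks) {
    ax <- c(ax,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s"/>',
              fmt(xf(tk)), fmt(y1), fmt(xf(tk)), fmt(y1 + 5)),
      sprintf('<text x="%s" y="%s" text-anchor="middle" stroke="none">%s</text>',
              fmt(xf(tk)), fmt(y1 + 17), sprintf("%g", tk)))
  }
  for (tk in yticks) {
    ax <- c(ax,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s"/>',
              fmt(MARGIN["left"] - 5), fmt(yf(tk)), fmt(MARGIN["left"]), fmt(yf(tk))),
      sprintf('<text x="%s" y="%s" text-anchor="end" stroke="none">%s</text>',
              fmt(MARGIN["left"] - 8), fmt(yf(tk) + 3), sprintf("%.3g", tk)))
  }
  ax <- c(ax,
    sprintf('<text x="%s" y="%s" text-anchor="middle" stroke="none">time before present</text>',
            fmt((xf(win[1]) + xf(win[2])) / 2), fmt(y1 + 34)),
    sprintf('<text x="%s" y="%s" text-anchor="middle" stroke="none" transform="rotate(-90 %s %s)">informativeness (%s)</text>',
            fmt(16), fmt((y0 + y1) / 2), fmt(16), fmt((y0 + y1) / 2),
            if (spec$show == "per_site") "per site" else "net"),
    "</g>")
  c(out, ax)
}

svg_doc <- function(spec, body) {
  paste(c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
                  spec$width, spec$height, spec$width, spec$height),
          body, "</svg>", ""), collapse = "\n")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the chronogram as SVG
#'
#' Draws the ultrametric tree in rectangular style on the time axis: tips at
#' the present, root at the tree depth, horizontal positions linear in time,
#' node order ladderized by clade size with alphabetical tie-breaks. Output
#' is deterministic: the same tree renders to the same bytes.
#'
#' @param tree a validated ultrametric tree.
#' @param spec a [plot_spec()].
#' @return a single string: a standalone SVG 1.1 document.
#' @export
render_tree_svg <- function(tree, spec = plot_spec()) {
  stopifnot(inherits(tree, "phylo"))
  xf <- x_transform(spec, tree_depth(tree))
  svg_doc(spec, tree_fragment(tree, spec, xf,
                              MARGIN["top"], spec$height - MARGIN["bottom"]))
}

#' Render informativeness profiles as SVG
#'
#' One polyline per displayed locus in its assigned color, with time and
#' informativeness axes; optional shaded epoch bands.
#'
#' @param profile a `pi_profile`.
#' @param spec a [plot_spec()].
#' @param loci which loci to draw (default all in the profile).
#' @return a single string: a standalone SVG 1.1 document.
#' @export
render_profiles_svg <- function(profile, spec = plot_spec(), loci = NULL) {
  stopifnot(inherits(profile, "pi_profile") || is.data.frame(profile))
  avail <- unique(profile$locus)
  if (is.null(loci)) loci <- avail
  if (!all(loci %in% avail))
    stop(sprintf("locus not in profile: %s (available: %s)",
                 paste(setdiff(loci, avail), collapse = ", "),
                 paste(avail, collapse = ", ")), call. = FALSE)
  xf <- x_transform(spec, attr(profile, "depth"))
  cols <- locus_colors(loci, spec)
  svg_doc(spec, profiles_fragment(profile, spec, xf,
                                  MARGIN["top"], spec$height - MARGIN["bottom"],
                                  loci, cols))
}

#' Render the combined tree-and-profiles figure
#'
#' The signature figure of informativeness profiling: the chronogram drawn
#' above the profiles, both panels sharing one x (time) transform so that
#' every divergence on the tree is vertically aligned with the
#' informativeness it would be resolved by.
#'
#' @inheritParams render_profiles_svg
#' @param tree a validated ultrametric tree.
#' @return a single string: a standalone SVG 1.1 document.
#' @examples
#' tr <- sim_ultrametric_tree(6, depth = 1, seed = 1)
#' sim <- simulate_locus(tr, 30, rates = list(shape = 1, mean = 1), seed = 2)
#' prof <- profile_loci(sim$true_rates, tree = tr, n_grid = 100)
#' svg <- render_figure(tr, prof)
#' @export
render_figure <- function(tree, profile, spec = plot_spec(), loci = NULL) {
  depth <- tree_depth(tree)
  avail <- unique(profile$locus)
  if (is.null(loci)) loci <- avail
  if (!all(loci %in% avail))
    stop(sprintf("locus not in profile: %s (available: %s)",
                 paste(setdiff(loci, avail), collapse = ", "),
                 paste(avail, collapse = ", ")), call. = FALSE)
  xf <- x_transform(spec, depth)
  cols <- locus_colors(loci, spec)
  inner_top <- MARGIN["top"]
  inner_bot <- spec$height - MARGIN["bottom"]
  split_y <- inner_top + 0.45 * (inner_bot - inner_top)
  body <- c(
    tree_fragment(tree, spec, xf, inner_top, split_y - 15),
    profiles_fragment(profile, spec, xf, split_y + 15, inner_bot, loci, cols)
  )
  svg_doc(spec, body)
}

#' Write an SVG document to disk
#'
#' @param svg SVG string from one of the render functions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(svg, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(svg, con, eos = NULL)
  invisible(path)
}
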