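#' Read a morphology from an SWC file
#'
#' Parses the standard 7-column SWC format (id, type, x, y, z, radius,
#' parent; 1-based sample ids, parent -1 for the root, coordinates and radii
#' in um), converts each maximal unbranched path into a section, and
#' assembles a `cell_model` with the recipe's channel densities assigned by
#' section kind (type 1 soma, 2 axon, 3 basal, 4 apical; terminal apical
#' sections become apical tips).  A soma given as a 3-point contour is
#' collapsed to a single cylinder whose diameter is taken from the middle
#' sample and whose length is the contour path length.  The original samples
#' are kept in `cell$swc` so that [write_swc()] round-trips coordinates.
#'
#' @param path SWC file path.
#' @param recipe Parameter recipe supplying densities, kinetics, pump and
#'   concentrations.
#' @param globals A [global_params()] object.
#' @return A `cell_model`.
#' @export
read_swc <- function(path, recipe = default_recipe(),
                     globals = global_params()) {
  pts <- parse_swc(path)
  sections <- swc_sections(pts)
  cell <- assemble_cell(sections, recipe, globals)
  cell$swc <- pts
  cell
}

parse_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  pts <- matrix(NA_real_, length(rows), 7)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (length(v) != 7 || anyNA(v))
      stop("malformed SWC row at line ", lineno[i])
    pts[i, ] <- v
  }
  pts <- as.data.frame(pts)
  names(pts) <- c("id", "type", "x", "y", "z", "r", "parent")
  seen <- integer(0)
  for (i in seq_len(nrow(pts))) {
    p <- pts$parent[i]
    if (p != -1 && !(p %in% seen))
      stop("parent id ", p, " not defined before line ", lineno[i])
    seen <- c(seen, pts$id[i])
  }
  pts
}

swc_kind <- function(type, terminal) {
  switch(as.character(type),
         "1" = "soma", "2" = "axon", "3" = "basal",
         "4" = if (terminal) "apical_tip" else "apical_trunk",
         "basal")
}

swc_sections <- function(pts) {
  soma_pts <- pts[pts$type == 1, ]
  if (nrow(soma_pts) == 0L) stop("SWC file has no soma sample")
  seg_len <- function(d) {
    if (nrow(d) < 2) return(max(2 * d$r[1], 1))
    sum(sqrt(diff(d$x)^2 + diff(d$y)^2 + diff(d$z)^2))
  }
  soma_diam <- 2 * soma_pts$r[ceiling(nrow(soma_pts) / 2)]
  soma_len <- max(seg_len(soma_pts), soma_diam)
  secs <- list(list(name = "soma", kind = "soma", length = soma_len,
                    diam0 = soma_diam, diam1 = soma_diam, parent = NA,
                    attach = NA, nseg = 1))
  sec_of_pt <- setNames(rep("soma", nrow(soma_pts)), soma_pts$id)
  nb_children <- table(factor(pts$parent, levels = pts$id))
  neur <- pts[pts$type != 1, ]
  counter <- new.env()
  for (i in seq_len(nrow(neur))) {
    p <- neur[i, ]
    par_id <- p$parent
    par_row <- pts[pts$id == par_id, ]
    starts_section <- par_row$type == 1 || nb_children[[as.character(par_id)]] > 1
    if (starts_section || is.na(sec_of_pt[as.character(par_id)])) {
      kind0 <- swc_kind(p$type, FALSE)
      n <- (get0(kind0, envir = counter, ifnotfound = 0)) + 1
      assign(kind0, n, envir = counter)
      nm <- paste0("swc_", kind0, "_", n)
      par_sec <- sec_of_pt[[as.character(par_id)]]
      d <- sqrt((p$x - par_row$x)^2 + (p$y - par_row$y)^2 +
                (p$z - par_row$z)^2)
      secs[[length(secs) + 1]] <- list(
        name = nm, kind = kind0, length = max(d, 1e-3),
        diam0 = 2 * p$r, diam1 = 2 * p$r, parent = par_sec,
        attach = if (par_row$type == 1) 0.5 else 1, nseg = NA)
    } else {
      nm <- sec_of_pt[[as.character(par_id)]]
      k <- which(vapply(secs, function(s) s$name == nm, TRUE))
      s <- secs[[k]]
      d <- sqrt((p$x - par_row$x)^2 + (p$y - par_row$y)^2 +
                (p$z - par_row$z)^2)
      s$length <- s$length + max(d, 1e-3)
      s$diam1 <- 2 * p$r
      secs[[k]] <- s
    }
    sec_of_pt[as.character(p$id)] <- nm
  }
  # terminal apical sections are tips
  sec_names <- vapply(secs, function(s) s$name, "")
  parents <- vapply(secs, function(s) ifelse(is.na(s$parent), "", s$parent), "")
  for (k in seq_along(secs)) {
    if (secs[[k]]$kind == "apical_trunk" &&
        !(secs[[k]]$name %in% parents))
      secs[[k]]$kind <- "apical_tip"
  }
  out <- do.call(rbind, lapply(secs, function(s)
    data.frame(s, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Write a cell morphology to an SWC file
#'
#' Cells read from SWC keep their original samples and round-trip exactly;
#' cells built from a recipe are written with generated straight-line
#' coordinates (axon along -y, apical dendrites along +y, basal along x).
#'
#' @param cell A `cell_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(cell, path) {
  if (!is.null(cell$swc)) {
    pts <- cell$swc
  } else {
    pts <- synth_swc_points(cell)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC export", con)
  apply(pts, 1, function(r)
    writeLines(paste(format(r[["id"]], trim = TRUE), r[["type"]],
                     r[["x"]], r[["y"]], r[["z"]], r[["r"]],
                     format(r[["parent"]], trim = TRUE)), con))
  invisible(path)
}

synth_swc_points <- function(cell) {
  dirs <- list(soma = c(0, 1, 0), hillock = c(0, -1, 0), ais = c(0, -1, 0),
               myelin = c(0, -1, 0), node = c(0, -1, 0), axon = c(0, -1, 0),
               apical_trunk = c(0, 1, 0), apical_tip = c(0.4, 0.9, 0),
               basal = c(1, 0.2, 0))
  sec <- cell$sections
  pos <- list(); pts <- list(); last_id <- 0
  end_id <- setNames(rep(NA_integer_, nrow(sec)), sec$name)
  end_xyz <- list()
  tipcount <- 0
  for (i in seq_len(nrow(sec))) {
    s <- sec[i, ]
    dvec <- dirs[[s$kind]]
    if (s$kind == "apical_tip" || s$kind == "basal") {
      tipcount <- tipcount + 1
      dvec <- dvec * c(if (tipcount %% 2) 1 else -1, 1, 1)
    }
    dvec <- dvec / sqrt(sum(dvec^2))
    if (is.na(s$parent)) {
      origin <- c(0, 0, 0); par_id <- -1
      type <- 1
    } else {
      origin <- end_xyz[[s$parent]]
      par_id <- end_id[[s$parent]]
      type <- switch(s$kind, soma = 1, basal = 3,
                     apical_trunk = 4, apical_tip = 4, 2)
    }
    npt <- 2
    for (k in seq_len(npt)) {
      frac <- k / npt
      xyz <- origin + dvec * s$length * frac
      last_id <- last_id + 1
      diam <- s$diam0 + (s$diam1 - s$diam0) * frac
      pts[[length(pts) + 1]] <- data.frame(
        id = last_id, type = type, x = round(xyz[1], 3),
        y = round(xyz[2], 3), z = round(xyz[3], 3), r = diam / 2,
        parent = if (k == 1) par_id else last_id - 1)
    }
    end_id[s$name] <- last_id
    end_xyz[[s$name]] <- origin + dvec * s$length
  }
  do.call(rbind, pts)
}
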