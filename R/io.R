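## Reading and writing the package's plain-text interchange formats:
## crystals (CSV with one row per centroid, or JSON with one record per
## crystal), persistence diagrams (CSV), and the tabular outputs of the
## classification and estimation stages.

#' Read crystals from the canonical CSV or JSON format
#'
#' CSV: one row per centroid with columns `id, a_nm, b_nm, c_nm,
#' alpha_deg, beta_deg, gamma_deg, fx, fy, fz` and optional `smiles`;
#' rows sharing an `id` form one crystal.  JSON: an array of objects with
#' fields `id`, `a_nm` ... `gamma_deg`, `centroids` (array of [fx, fy,
#' fz] triples) and optional `smiles`.
#'
#' @param path File path; format chosen by extension (`.csv` / `.json`).
#' @return A named list of [crystal_centroids()] objects.
#' @export
read_crystals <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
    out <- lapply(recs, function(r) {
      crystal_centroids(
        cell_parameters(r$a_nm, r$b_nm, r$c_nm,
                        r$alpha_deg, r$beta_deg, r$gamma_deg),
        do.call(rbind, lapply(r$centroids, unlist)),
        smiles = r$smiles, id = r$id)
    })
    names(out) <- vapply(out, function(x) x$id %||% "", "")
    return(out)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "a_nm", "b_nm", "c_nm", "alpha_deg", "beta_deg",
            "gamma_deg", "fx", "fy", "fz")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("crystal CSV lacks columns: ", paste(missing, collapse = ", "))
  out <- lapply(split(df, df$id), function(g) {
    crystal_centroids(
      cell_parameters(g$a_nm[1], g$b_nm[1], g$c_nm[1],
                      g$alpha_deg[1], g$beta_deg[1], g$gamma_deg[1]),
      as.matrix(g[, c("fx", "fy", "fz")]),
      smiles = if ("smiles" %in% names(g)) g$smiles[1] else NULL,
      id = as.character(g$id[1]))
  })
  out[order(names(out))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write crystals to the canonical CSV or JSON format
#'
#' @param crystals A list of [crystal_centroids()] objects (or a single
#'   one); unnamed crystals are labelled `crystal_1`, ...
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_crystals <- function(crystals, path) {
  if (inherits(crystals, "crystal_centroids")) crystals <- list(crystals)
  ids <- vapply(seq_along(crystals), function(i)
    crystals[[i]]$id %||% sprintf("crystal_%d", i), "")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(seq_along(crystals), function(i) {
      cr <- crystals[[i]]; cl <- cr$cell
      r <- list(id = ids[i], a_nm = cl$a, b_nm = cl$b, c_nm = cl$c,
                alpha_deg = cl$alpha, beta_deg = cl$beta,
                gamma_deg = cl$gamma,
                centroids = lapply(seq_len(nrow(cr$centroids)),
                                   function(k) cr$centroids[k, ]))
      if (!is.null(cr$smiles)) r$smiles <- cr$smiles
      r
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  rows <- do.call(rbind, lapply(seq_along(crystals), function(i) {
    cr <- crystals[[i]]; cl <- cr$cell
    data.frame(id = ids[i], a_nm = cl$a, b_nm = cl$b, c_nm = cl$c,
               alpha_deg = cl$alpha, beta_deg = cl$beta,
               gamma_deg = cl$gamma,
               fx = cr$centroids[, 1], fy = cr$centroids[, 2],
               fz = cr$centroids[, 3],
               smiles = cr$smiles %||% NA_character_)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a diagram set to CSV
#'
#' One row per (birth, death) pair, columns `q`, `birth_nm`, `death_nm`;
#' infinite deaths are written as `inf`.
#'
#' @param diagrams A `"diagram_set"` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_diagrams <- function(diagrams, path) {
  rows <- do.call(rbind, lapply(names(diagrams), function(q) {
    m <- unclass(diagrams[[q]])
    if (nrow(m) == 0) return(NULL)
    data.frame(q = as.integer(q), birth_nm = m[, 1],
               death_nm = ifelse(is.infinite(m[, 2]), "inf",
                                 format(m[, 2], digits = 17)))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a diagram set written by [write_diagrams()]
#'
#' @param path CSV path.
#' @return A `"diagram_set"` object.
#' @export
read_diagrams <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dg <- lapply(0:2, function(q) {
    g <- df[df$q == q, , drop = FALSE]
    d <- ifelse(g$death_nm %in% c("inf", "Inf"), Inf,
                as.numeric(g$death_nm))
    new_diagram(cbind(g$birth_nm, d), q)
  })
  names(dg) <- as.character(0:2)
  structure(dg, class = "diagram_set")
}

#' Tabulate lattice assignments
#'
#' @param assignments A list of `"lattice_assignment"` objects (or one).
#' @return A data frame with columns `id`, `assigned_type`, `score_P`,
#'   `score_C`, `score_I`, `score_F`, `epsilon`.
#' @export
assignment_table <- function(assignments) {
  if (inherits(assignments, "lattice_assignment"))
    assignments <- list(assignments)
  do.call(rbind, lapply(seq_along(assignments), function(i) {
    a <- assignments[[i]]
    data.frame(id = a$id %||% sprintf("crystal_%d", i),
               assigned_type = a$type,
               score_P = a$scores[["P"]], score_C = a$scores[["C"]],
               score_I = a$scores[["I"]], score_F = a$scores[["F"]],
               epsilon = a$epsilon)
  }))
}

#' Tabulate estimated ellipsoid shapes
#'
#' @param shapes A list of `"ellipsoid_shape"` objects (or one).
#' @param cells Optional list of matching [cell_parameters()] to add the
#'   realized packing fraction column (Z V / V_cell).
#' @param ids Optional character vector of row labels.
#' @return A data frame with columns `id`, `type`, `r1_nm`, `r2_nm`,
#'   `r3_nm`, `volume_nm3`, `volume_cm3_per_mol` and, when `cells` is
#'   given, `packing_fraction`.
#' @export
shape_table <- function(shapes, cells = NULL, ids = NULL) {
  if (inherits(shapes, "ellipsoid_shape")) shapes <- list(shapes)
  z_per_type <- c(P = 1, C = 2, I = 2, F = 4)
  do.call(rbind, lapply(seq_along(shapes), function(i) {
    s <- shapes[[i]]
    row <- data.frame(
      id = if (!is.null(ids)) ids[i] else sprintf("crystal_%d", i),
      type = s$type,
      r1_nm = s$radii[1], r2_nm = s$radii[2], r3_nm = s$radii[3],
      volume_nm3 = s$volume_nm3,
      volume_cm3_per_mol = ellipsoid_volume(s, per_mole = TRUE))
    if (!is.null(cells)) {
      vcell <- abs(det(cell_matrix(cells[[i]])))
      row$packing_fraction <-
        z_per_type[[s$type]] * s$volume_nm3 / vcell
    }
    row
  }))
}
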