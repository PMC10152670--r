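#' Parse a PDB file into a structure ensemble
#'
#' Reads fixed-width `ATOM`/`HETATM` records; `MODEL`/`ENDMDL` blocks become
#' separate models. Alternate locations other than blank or `A` are dropped.
#' Elements missing from columns 77-78 are derived from the atom name.
#' Malformed (truncated) atom records raise an error naming the line.
#'
#' @param x path to a PDB file, or a character vector of PDB lines.
#' @return an object of class `"structure_ensemble"`: a list with `models`
#'   (each a data frame of atoms: `serial`, `name`, `altloc`, `resname`,
#'   `chain`, `resno`, `x`, `y`, `z`, `occupancy`, `bfactor`, `element`) and
#'   `shared_topology` (TRUE when atom counts and names align across models).
#' @export
read_pdb <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1L]]
  } else {
    x
  }
  models <- list()
  current <- list()
  in_model <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    rec <- substr(line, 1L, 6L)
    if (startsWith(rec, "MODEL")) {
      in_model <- TRUE
      current <- list()
    } else if (startsWith(rec, "ENDMDL")) {
      models[[length(models) + 1L]] <- current
      current <- list()
      in_model <- FALSE
    } else if (rec == "ATOM  " || rec == "HETATM") {
      if (nchar(line) < 54L) {
        stop(sprintf("malformed ATOM/HETATM record at line %d (only %d characters)",
                     i, nchar(line)))
      }
      altloc <- substr(line, 17L, 17L)
      if (!altloc %in% c(" ", "A")) next
      name <- trimws(substr(line, 13L, 16L))
      element <- if (nchar(line) >= 78L) trimws(substr(line, 77L, 78L)) else ""
      if (element == "") element <- .element_from_name(name)
      current[[length(current) + 1L]] <- data.frame(
        serial = as.integer(substr(line, 7L, 11L)),
        name = name,
        altloc = trimws(altloc),
        resname = trimws(substr(line, 18L, 20L)),
        chain = trimws(substr(line, 22L, 22L)),
        resno = as.integer(substr(line, 23L, 26L)),
        x = as.numeric(substr(line, 31L, 38L)),
        y = as.numeric(substr(line, 39L, 46L)),
        z = as.numeric(substr(line, 47L, 54L)),
        occupancy = if (nchar(line) >= 60L) as.numeric(substr(line, 55L, 60L)) else 1,
        bfactor = if (nchar(line) >= 66L) as.numeric(substr(line, 61L, 66L)) else 0,
        element = element,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(current) > 0L) models[[length(models) + 1L]] <- current
  if (length(models) == 0L) stop("no ATOM/HETATM records found")
  models <- lapply(models, function(m) {
    df <- do.call(rbind, m)
    rownames(df) <- NULL
    df
  })
  structure_ensemble(models)
}

.element_from_name <- function(name) {
  core <- gsub("[0-9']", "", name)
  if (nchar(core) == 0L) stop("cannot derive element from atom name '", name, "'")
  toupper(substr(core, 1L, 1L))
}

#' Build a structure ensemble from atom tables
#'
#' @param models a single atom data frame or a list of them.
#' @return a `"structure_ensemble"`.
#' @export
structure_ensemble <- function(models) {
  if (is.data.frame(models)) models <- list(models)
  stopifnot(length(models) >= 1L)
  n <- vapply(models, nrow, integer(1L))
  shared <- length(unique(n)) == 1L &&
    all(vapply(models, function(m) identical(m$name, models[[1L]]$name), logical(1L)))
  structure(list(models = models, shared_topology = shared),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure ensemble: %d model(s), %d atoms%s\n",
              length(x$models), nrow(x$models[[1L]]),
              if (x$shared_topology) ", shared topology" else ""))
  invisible(x)
}

#' Serialize a structure ensemble to PDB text
#'
#' Coordinates are written at the standard fixed-width precision (1e-3 A),
#' so a write/read round trip preserves them to that precision. Ensembles
#' with more than one model are wrapped in `MODEL`/`ENDMDL` blocks.
#'
#' @param ensemble a `"structure_ensemble"` (or single atom data frame).
#' @param path optional output file.
#' @return the PDB lines, invisibly when `path` is given.
#' @export
write_pdb <- function(ensemble, path = NULL) {
  if (is.data.frame(ensemble)) ensemble <- structure_ensemble(ensemble)
  multi <- length(ensemble$models) > 1L
  lines <- character(0L)
  for (k in seq_along(ensemble$models)) {
    m <- ensemble$models[[k]]
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", k))
    atom_name <- ifelse(nchar(m$name) >= 4L, substr(m$name, 1L, 4L),
                        sprintf(" %-3s", m$name))
    lines <- c(lines, sprintf(
      "ATOM  %5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      m$serial, atom_name, ifelse(m$altloc == "", " ", m$altloc),
      m$resname, m$chain, m$resno, m$x, m$y, m$z, m$occupancy, m$bfactor,
      m$element))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Select atoms of a model
#'
#' All supplied filters are combined with AND; `NULL` filters are ignored.
#'
#' @param model an atom data frame (one model of an ensemble).
#' @param chain,resno,resname,name,element optional filters (vectors allowed).
#' @return integer atom indices.
#' @export
select_atoms <- function(model, chain = NULL, resno = NULL, resname = NULL,
                         name = NULL, element = NULL) {
  keep <- rep(TRUE, nrow(model))
  if (!is.null(chain)) keep <- keep & model$chain %in% chain
  if (!is.null(resno)) keep <- keep & model$resno %in% resno
  if (!is.null(resname)) keep <- keep & model$resname %in% resname
  if (!is.null(name)) keep <- keep & model$name %in% name
  if (!is.null(element)) keep <- keep & model$element %in% element
  which(keep)
}
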