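#' File formats
#'
#' Readers/writers for the PDB v3.3 coordinate subset (ATOM/TER/CRYST1,
#' coordinates at %8.3f), CCP4/MRC mode-2 (float32) volumetric maps with
#' X,Y,Z axis order, a whitespace-separated plain-text reflection format,
#' and a JSON-lines dataset manifest.
#'
#' @name file-formats
NULL

SPACE_GROUP_STRINGS <- c(P1 = "P 1", P21 = "P 1 21 1")
SPACE_GROUP_NUMBERS <- c(P1 = 1L, P21 = 4L)

# element inference from atom-name columns when the element field is blank
infer_element <- function(name) {
  n <- gsub("[ 0-9']", "", name)
  first <- substr(n, 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "H"), first, first)
}

#' Read a PDB coordinate file
#'
#' Parses ATOM/HETATM and CRYST1 records. The element is taken from
#' columns 77-78, falling back to inference from the atom name; 1-based
#' residue numbering is preserved.
#'
#' @param path file path.
#' @return list: `atoms` (tibble, one row per atom, with `chain`), `cell`
#'   (length-3 or NULL), `space_group` (`"P1"`, `"P21"` or NULL).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  lines <- readLines(path)
  cell <- NULL; sg <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) > 0) {
    cell <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                         substr(cr[1], 25, 33)))
    sg_str <- trimws(substr(cr[1], 56, 66))
    sg <- names(SPACE_GROUP_STRINGS)[match(sg_str, SPACE_GROUP_STRINGS)]
  }
  at <- grep("^(ATOM  |HETATM)", lines)
  if (length(at) == 0) rlang::abort("no ATOM records")
  parse_line <- function(i) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      rlang::abort(sprintf("malformed ATOM record at line %d", i))
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      rlang::abort(sprintf("malformed coordinates at line %d", i))
    }
    elem <- trimws(substr(ln, 77, 78))
    if (elem == "") elem <- infer_element(substr(ln, 13, 16))
    tibble::tibble(
      resid = as.integer(substr(ln, 23, 26)),
      resname = trimws(substr(ln, 18, 20)),
      atom = trimws(substr(ln, 13, 16)),
      element = elem,
      chain = substr(ln, 22, 22),
      x = xyz[1], y = xyz[2], z = xyz[3],
      b = as.numeric(substr(ln, 61, 66)),
      occ = as.numeric(substr(ln, 55, 60)))
  }
  atoms <- dplyr::bind_rows(lapply(at, parse_line))
  list(atoms = atoms, cell = cell, space_group = sg)
}

#' Write a PDB coordinate file
#'
#' @param atoms atom table (a `chain` column is honoured, default "A").
#' @param path output path.
#' @param cell optional length-3 cell for a CRYST1 record (angles 90).
#' @param space_group `"P1"` or `"P21"` (written as "P 1" / "P 1 21 1").
#' @export
write_pdb <- function(atoms, path, cell = NULL, space_group = "P1") {
  lines <- character(0)
  if (!is.null(cell)) {
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                     cell[1], cell[2], cell[3], 90, 90, 90,
                     SPACE_GROUP_STRINGS[[space_group]], 1L)
  }
  chain <- if ("chain" %in% names(atoms)) atoms$chain else rep("A", nrow(atoms))
  occ <- if ("occ" %in% names(atoms)) atoms$occ else rep(1, nrow(atoms))
  name_field <- ifelse(nchar(atoms$atom) < 4, paste0(" ", atoms$atom),
                       atoms$atom)
  rec <- sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 seq_len(nrow(atoms)), name_field, atoms$resname, chain,
                 atoms$resid, atoms$x, atoms$y, atoms$z, occ, atoms$b,
                 atoms$element)
  writeLines(c(lines, rec, "TER", "END"), path)
  invisible(path)
}

#' Write a unit cell to PDB
#'
#' All symmetry copies are written as separate chains (A, B, ...).
#' @param cell a `unit_cell`.
#' @param path output path.
#' @export
write_cell_pdb <- function(cell, path) {
  atoms <- cell$atoms
  atoms$chain <- LETTERS[atoms$copy]
  write_pdb(atoms, path, cell = cell$cell, space_group = cell$space_group)
}

# ---- CCP4/MRC maps ---------------------------------------------------------

#' Write a map in CCP4/MRC mode-2 (float32) format
#'
#' Axis order is fixed X,Y,Z (MAPC/MAPR/MAPS = 1,2,3); the header carries
#' the grid shape, cell and space-group number (1 for P1, 4 for P21).
#'
#' @param map a `map_grid`.
#' @param path output path.
#' @param space_group `"P1"` or `"P21"`.
#' @export
write_map <- function(map, path, space_group = "P1") {
  n <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- map$values
  wi(n)                          # NC NR NS
  wi(2)                          # MODE 2: float32
  wi(c(0, 0, 0))                 # NCSTART NRSTART NSSTART
  wi(n)                          # NX NY NZ sampling intervals
  wf(map$cell)                   # cell lengths
  wf(c(90, 90, 90))              # cell angles
  wi(c(1, 2, 3))                 # MAPC MAPR MAPS: X fast, Y medium, Z slow
  wf(c(min(v), max(v), mean(v))) # AMIN AMAX AMEAN
  wi(SPACE_GROUP_NUMBERS[[space_group]])
  wi(0)                          # NSYMBT
  wi(rep(0, 25))                 # EXTRA
  wf(c(0, 0, 0))                 # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # little-endian stamp
  wf(stats::sd(v))               # RMS
  wi(0)                          # NLABL
  writeBin(raw(800), con)        # 10 empty labels
  wf(as.vector(v))               # x fastest (column-major)
  invisible(path)
}

#' Read a CCP4/MRC mode-2 map
#'
#' @param path file path.
#' @param flavor flavor tag for the returned `map_grid`.
#' @return a `map_grid` (values at float32 precision).
#' @export
read_map <- function(path, flavor = "density") {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", n = k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", n = k, size = 4, endian = "little")
  n <- ri(3)
  mode <- ri(1)
  if (mode != 2) rlang::abort("only mode-2 (float32) maps are supported")
  ri(3)               # starts
  ri(3)               # intervals
  cell <- rf(3)
  rf(3)               # angles
  axes <- ri(3)
  if (!identical(axes, c(1L, 2L, 3L))) {
    rlang::abort("only X,Y,Z axis order is supported")
  }
  rf(3)               # min max mean
  ri(1)               # ISPG
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  vals <- rf(prod(n))
  map_grid(array(vals, dim = n), cell, flavor)
}

# ---- reflection text format ------------------------------------------------

#' Write reflections as plain text
#'
#' Two header lines (cell and d_min) followed by one line per reflection:
#' `h k l amplitude phase_deg d`.
#'
#' @param refl a [reflection_set()].
#' @param path output path.
#' @export
write_reflections <- function(refl, path) {
  cell <- attr(refl, "cell")
  hdr <- c(sprintf("# cell %.6f %.6f %.6f", cell[1], cell[2], cell[3]),
           sprintf("# d_min %.6f", attr(refl, "d_min")))
  body <- sprintf("%d %d %d %.8g %.6f %.6f", refl$h, refl$k, refl$l,
                  Mod(refl$f), Arg(refl$f) * 180 / pi, refl$d)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read reflections from plain text
#' @param path file path (format of [write_reflections()]).
#' @return a [reflection_set()].
#' @export
read_reflections <- function(path) {
  lines <- readLines(path)
  cell <- as.numeric(strsplit(lines[1], " +")[[1]][3:5])
  d_min <- as.numeric(strsplit(lines[2], " +")[[1]][3])
  body <- utils::read.table(text = lines[-(1:2)],
                            col.names = c("h", "k", "l", "amp", "phase", "d"))
  reflection_set(tibble::tibble(
    h = as.integer(body$h), k = as.integer(body$k), l = as.integer(body$l),
    f = complex(modulus = body$amp, argument = body$phase * pi / 180),
    d = body$d), cell = cell, d_min = d_min)
}

# ---- dataset export --------------------------------------------------------

#' Write a dataset of examples to disk
#'
#' Per example: Patterson, ground-truth and partial-template maps in CCP4
#' format plus a JSON-lines manifest (one record per example: id, shape,
#' bin, omission records, seed).
#'
#' @param examples list of `dataset_example`s.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(examples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(dir, "manifest.jsonl")
  con <- file(manifest, "w")
  on.exit(close(con))
  for (i in seq_along(examples)) {
    ex <- examples[[i]]
    id <- sprintf("ex%04d", i)
    write_map(ex$patterson, file.path(dir, paste0(id, "_patterson.ccp4")),
              space_group = "P21")
    write_map(ex$ground_truth, file.path(dir, paste0(id, "_truth.ccp4")),
              space_group = "P21")
    for (j in seq_along(ex$partials)) {
      write_map(ex$partials[[j]]$map,
                file.path(dir, sprintf("%s_partial%d.ccp4", id, j)),
                space_group = "P21")
    }
    rec <- list(id = id,
                shape = dim(ex$ground_truth$values),
                bin = as.list(ex$bin),
                omissions = lapply(ex$partials, function(p) as.list(p$record)),
                source_id = ex$provenance$source_id,
                seed = ex$provenance$seed)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(manifest)
}
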