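# MRC/CCP4 map input/output and PDB structure reading.
#
# Internally every map is held in canonical order: array index (i, j, k)
# corresponds to spatial (x, y, z), voxel values are samples at voxel
# CENTRES, and the Angstrom position of index (i, j, k) (0-based) is
# origin + (i, j, k) * voxel_size.

#' Construct a voxel map
#'
#' A `voxel_map` is a 3-D density array in canonical x,y,z index order plus
#' the geometry needed to place it in Angstrom space: per-axis voxel spacing
#' (possibly anisotropic) and the Angstrom coordinate of the centre of voxel
#' (0,0,0).
#'
#' @param data 3-D numeric array, indexed `[ix, iy, iz]`.
#' @param voxel_size numeric length-3 (or scalar), Angstrom per voxel along
#'   x, y, z; all components must be positive.
#' @param origin numeric length-3, Angstrom coordinate of the centre of the
#'   first voxel.
#' @param resolution optional reported map resolution in Angstrom.
#' @return An object of class `voxel_map` with fields `data`, `voxel_size`,
#'   `origin`, `shape`, `resolution`.
#' @export
voxel_map <- function(data, voxel_size, origin = c(0, 0, 0),
                      resolution = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array, got ", length(dim(data)),
         " dimension(s)")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel sizes must be positive and finite: ",
         paste(signif(voxel_size, 4), collapse = ", "))
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(origin))) stop("origin must be finite")
  structure(list(data = data, voxel_size = voxel_size, origin = origin,
                 shape = dim(data), resolution = resolution),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  cat("Cryo-EM voxel map\n")
  cat("  shape      :", paste(x$shape, collapse = " x "), "voxels\n")
  cat("  voxel size :", paste(signif(x$voxel_size, 4), collapse = ", "),
      "Angstrom\n")
  cat("  origin     :", paste(signif(x$origin, 4), collapse = ", "),
      "Angstrom\n")
  rng <- range(x$data)
  cat("  density    : [", signif(rng[1], 4), ",", signif(rng[2], 4), "]\n")
  if (!is.null(x$resolution))
    cat("  resolution :", x$resolution, "Angstrom\n")
  invisible(x)
}

#' Voxel index to Angstrom coordinate
#'
#' Maps 0-based voxel indices to the Angstrom positions of the voxel
#' centres. The inverse for in-grid points is [coord_to_index()].
#'
#' @param map a `voxel_map`.
#' @param ijk integer matrix (N x 3) or vector of 0-based indices.
#' @return N x 3 matrix of Angstrom coordinates.
#' @export
index_to_coord <- function(map, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  sweep(sweep(ijk, 2L, map$voxel_size, `*`), 2L, map$origin, `+`)
}

#' Angstrom coordinate to voxel index
#'
#' Exact inverse of [index_to_coord()]; returns fractional 0-based indices
#' (not rounded), so integer outputs indicate voxel centres.
#'
#' @param map a `voxel_map`.
#' @param xyz numeric matrix (N x 3) of Angstrom coordinates.
#' @return N x 3 matrix of fractional 0-based voxel indices.
#' @export
coord_to_index <- function(map, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  sweep(sweep(xyz, 2L, map$origin, `-`), 2L, map$voxel_size, `/`)
}

#' Angstrom bounding hull of the voxel centres
#'
#' @param map a `voxel_map`.
#' @return 3 x 2 matrix: per-axis minimum and maximum voxel-centre
#'   coordinate in Angstrom.
#' @export
map_bounds <- function(map) {
  cbind(map$origin, map$origin + (map$shape - 1) * map$voxel_size)
}

# ---- MRC format ------------------------------------------------------------

.mrc_header_words <- 256L  # 1024-byte header of 4-byte words

#' Read an MRC/CCP4 density map
#'
#' Parses the 1024-byte MRC header, reads the voxel block (modes 0, 1, 2
#' and 6; integer modes are converted to numeric), and canonicalizes the
#' axis order: the `mapc`/`mapr`/`maps` header correspondence is resolved by
#' transposing the data so that array index order is (x, y, z). The origin
#' is taken from the MRC2000 origin fields when set, otherwise from
#' `nstart * voxel_size`.
#'
#' @param path path to an MRC/CCP4 file.
#' @return a [voxel_map()].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("cannot read map: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nxyz <- ints[1:3]; mode <- ints[4]; nstart <- ints[5:7]; mxyz <- ints[8:10]
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  readBin(con, "numeric", n = 3L, size = 4L, endian = "little")  # cell angles
  mapcrs <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  readBin(con, "numeric", n = 3L, size = 4L, endian = "little")  # dmin/max/mean
  ispg <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  nsymbt <- ispg[2]
  readBin(con, "integer", n = 25L, size = 4L, endian = "little")  # extra
  org <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  readBin(con, "raw", n = 16L)  # MAP stamp + machine stamp + rms
  # header diagnostics for errors
  diag <- sprintf("n=(%s) mode=%d map_crs=(%s) cella=(%s)",
                  paste(nxyz, collapse = ","), mode,
                  paste(mapcrs, collapse = ","),
                  paste(signif(cella, 5), collapse = ","))
  if (any(nxyz <= 0) || length(nxyz) != 3L)
    stop("map is not 3-D [", diag, "]")
  if (!all(sort(mapcrs) == 1:3))
    stop("invalid axis correspondence in header [", diag, "]")
  if (any(mxyz <= 0) || any(cella <= 0))
    stop("zero or negative voxel size in header [", diag, "]")
  seek(con, 1024L + nsymbt)
  n_vox <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n_vox, size = 1L,
                             signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = n_vox, size = 2L,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = n_vox, size = 4L, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n_vox, size = 2L,
                             signed = FALSE, endian = "little")),
    stop("unsupported MRC mode ", mode, " [", diag, "]"))
  if (length(vals) != n_vox)
    stop("truncated voxel block: expected ", n_vox, " values, got ",
         length(vals), " [", diag, "]")
  arr <- array(vals, dim = nxyz)  # file order: (columns, rows, sections)
  # file axis m is spatial axis mapcrs[m]; canonicalize to (x, y, z)
  arr <- aperm(arr, match(1:3, mapcrs))
  voxel_size <- cella / mxyz  # indexed by spatial axis
  if (all(org == 0) && any(nstart != 0)) {
    org_sp <- numeric(3L)
    org_sp[mapcrs] <- nstart  # nstart follows file axis order
    org <- org_sp * voxel_size
  }
  voxel_map(arr, voxel_size = voxel_size, origin = org)
}

#' Write a map in MRC format
#'
#' Writes mode-2 (float32) MRC with MRC2000 origin fields. `axis_order`
#' selects the file's column/row/section to spatial-axis correspondence
#' (`mapc`,`mapr`,`maps`); the default writes canonical x,y,z order.
#'
#' @param map a [voxel_map()].
#' @param path output file path.
#' @param axis_order permutation of 1:3; spatial axes stored as file
#'   columns, rows, sections. Mainly useful for producing maps with
#'   non-canonical axis order.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path, axis_order = 1:3) {
  stopifnot(inherits(map, "voxel_map"))
  if (!all(sort(axis_order) == 1:3)) stop("axis_order must permute 1:3")
  arr <- aperm(map$data, axis_order)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(dim(arr))              # nx, ny, nz (file order)
  wi(2L)                    # mode 2: float32
  wi(c(0L, 0L, 0L))         # nstart
  wi(map$shape)             # mx, my, mz (spatial)
  wf(map$shape * map$voxel_size)  # cella
  wf(c(90, 90, 90))         # cell angles
  wi(axis_order)            # mapc, mapr, maps
  wf(c(min(map$data), max(map$data), mean(map$data)))
  wi(c(1L, 0L))             # ispg, nsymbt
  wi(integer(25L))          # extra
  wf(map$origin)            # MRC2000 origin (spatial x, y, z)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(map$data))
  wi(0L)                    # nlabl
  writeBin(raw(800L), con)  # labels
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  invisible(path)
}

# ---- PDB structures --------------------------------------------------------

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL", "MSE", "SEC", "PYL")

#' Construct an atom set
#'
#' @param name atom names (e.g. `"CA"`).
#' @param element element symbols.
#' @param resno residue indices.
#' @param chain chain identifiers.
#' @param x,y,z Cartesian coordinates in Angstrom.
#' @param resid residue 3-letter codes (used to flag alpha carbons).
#' @return data frame of class `atom_set` with an `is_calpha` flag.
#' @export
atom_set <- function(name, element, resno, chain, x, y, z,
                     resid = "ALA") {
  if (!all(is.finite(c(x, y, z)))) stop("atom coordinates must be finite")
  df <- data.frame(name = as.character(name),
                   element = as.character(element),
                   resno = as.integer(resno),
                   chain = as.character(chain),
                   resid = rep_len(as.character(resid), length(name)),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  df$is_calpha <- df$name == "CA" & df$resid %in% .standard_aa
  class(df) <- c("atom_set", "data.frame")
  df
}

#' Read atoms from a PDB file
#'
#' Parses ATOM records (HETATM and waters excluded unless `include_het`).
#'
#' @param path path to a PDB file.
#' @param include_het also keep HETATM records (waters always excluded).
#' @return an [atom_set()].
#' @export
read_structure <- function(path, include_het = FALSE) {
  if (!file.exists(path)) stop("cannot read structure: no such file: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (include_het) keep <- keep | (at$type == "HETATM" & at$resid != "HOH")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms parsed from ", path)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(at$elety), 1L, 1L)
  atom_set(name = trimws(at$elety), element = trimws(elem),
           resno = at$resno, chain = at$chain,
           x = at$x, y = at$y, z = at$z, resid = trimws(at$resid))
}

#' Write an atom set as a PDB file
#'
#' @param atoms an [atom_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  stopifnot(inherits(atoms, "atom_set"))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$resno, resid = atoms$resid,
                   elety = atoms$name, chain = atoms$chain,
                   elesy = atoms$element)
  invisible(path)
}
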