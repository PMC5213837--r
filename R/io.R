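#' @include AllClasses.R utils.R
NULL

# ---- mesh formats -------------------------------------------------------

#' Read and write OFF meshes
#'
#' ASCII OFF with triangular faces only (a face with a different vertex
#' count is rejected with a message). Vertex indices are 0-based on disk,
#' 1-based in memory.
#'
#' @param path File path.
#' @param mesh A [TriangleMesh-class].
#' @param areaLabels Optional labels to attach on read (see
#'   [readLabelsTSV()] for the companion table).
#' @return `readMeshOFF` returns a [TriangleMesh-class].
#' @export
readMeshOFF <- function(path, areaLabels = character(0)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!grepl("^OFF", lines[1]))
    stop(sprintf("%s: not an OFF file (missing OFF header)", path),
         call. = FALSE)
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtx <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  dimnames(vtx) <- NULL
  faces <- matrix(0L, nf, 3L)
  for (i in seq_len(nf)) {
    f <- as.integer(strsplit(trimws(lines[2 + nv + i]), "\\s+")[[1]])
    if (f[1] != 3L)
      stop(sprintf("%s: face %d has %d vertices; only triangles supported",
                   path, i, f[1]), call. = FALSE)
    faces[i, ] <- f[2:4] + 1L
  }
  new("TriangleMesh", vertices = vtx, triangles = faces,
      areaLabels = areaLabels)
}

#' @rdname readMeshOFF
#' @export
writeMeshOFF <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nVertices(mesh), nTriangles(mesh)), con)
  writeLines(apply(mesh@vertices, 1, function(v)
    paste(sprintf("%.17g", v), collapse = " ")), con)
  writeLines(apply(mesh@triangles - 1L, 1, function(f)
    paste(c("3", f), collapse = " ")), con)
  invisible(path)
}

#' Read and write PLY meshes
#'
#' Supports ASCII and binary little-endian PLY 1.0 with float/double
#' vertex coordinates and triangular faces; writing is ASCII.
#'
#' @param path File path.
#' @param mesh A [TriangleMesh-class].
#' @param areaLabels Optional labels to attach on read.
#' @return `readMeshPLY` returns a [TriangleMesh-class].
#' @export
readMeshPLY <- function(path, areaLabels = character(0)) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    l <- readBin(con, "raw", n = 1)
    line <- raw(0)
    while (length(l) && l != as.raw(10L)) {
      line <- c(line, l)
      l <- readBin(con, "raw", n = 1)
    }
    header <- c(header, rawToChar(line))
    if (trimws(utils::tail(header, 1)) == "end_header") break
    if (length(header) > 200)
      stop(sprintf("%s: PLY header not terminated", path), call. = FALSE)
  }
  if (trimws(header[1]) != "ply")
    stop(sprintf("%s: not a PLY file", path), call. = FALSE)
  fmt <- strsplit(trimws(header[grepl("^format", header)]), "\\s+")[[1]][2]
  elems <- list(); cur <- NULL
  for (h in header) {
    tok <- strsplit(trimws(h), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(n = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props <- c(elems[[cur]]$props, list(tok[-1]))
    }
  }
  nv <- elems$vertex$n; nf <- elems$face$n
  typeSize <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2,
                ushort = 2, int16 = 2, uint16 = 2, int = 4, uint = 4,
                int32 = 4, uint32 = 4, float = 4, float32 = 4,
                double = 8, float64 = 8)
  readScalar <- function(type) {
    sz <- typeSize[[type]]
    what <- if (type %in% c("float", "float32", "double", "float64"))
      "double" else "integer"
    readBin(con, what, n = 1, size = sz, endian = "little",
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }
  if (fmt == "ascii") {
    rest <- readLines(con)
    rest <- rest[nzchar(trimws(rest))]
    vtx <- do.call(rbind, lapply(rest[1:nv], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
    dimnames(vtx) <- NULL
    faces <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      f <- as.integer(strsplit(trimws(rest[nv + i]), "\\s+")[[1]])
      if (f[1] != 3L)
        stop(sprintf("%s: face %d is not a triangle", path, i),
             call. = FALSE)
      faces[i, ] <- f[2:4] + 1L
    }
  } else if (fmt == "binary_little_endian") {
    vprops <- elems$vertex$props
    vtx <- matrix(0, nv, 3)
    for (i in seq_len(nv)) {
      vals <- numeric(0)
      for (p in vprops) vals <- c(vals, readScalar(p[[1]]))
      vtx[i, ] <- vals[1:3]
    }
    fprop <- elems$face$props[[1]]  # list <countType> <indexType> ...
    faces <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- readScalar(fprop[[2]])
      if (cnt != 3L)
        stop(sprintf("%s: face %d is not a triangle", path, i),
             call. = FALSE)
      faces[i, ] <- vapply(1:3, function(k)
        as.integer(readScalar(fprop[[3]])), integer(1)) + 1L
    }
  } else {
    stop(sprintf("%s: unsupported PLY format %s", path, fmt),
         call. = FALSE)
  }
  new("TriangleMesh", vertices = vtx, triangles = faces,
      areaLabels = areaLabels)
}

#' @rdname readMeshPLY
#' @export
writeMeshPLY <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nVertices(mesh)),
               "property double x", "property double y",
               "property double z",
               sprintf("element face %d", nTriangles(mesh)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(mesh@vertices, 1, function(v)
    paste(sprintf("%.17g", v), collapse = " ")), con)
  writeLines(apply(mesh@triangles - 1L, 1, function(f)
    paste(c("3", f), collapse = " ")), con)
  invisible(path)
}

# ---- label / classification tables --------------------------------------

#' Read and write triangle label tables
#'
#' TSV with columns `triangle_id` (0-based), `area` and optionally
#' `module`.
#'
#' @param path File path.
#' @param area Character vector of area labels.
#' @param module Optional planted/detected module ids.
#' @return `readLabelsTSV` returns the data.frame.
#' @export
writeLabelsTSV <- function(area, path, module = NULL) {
  df <- data.frame(triangle_id = seq_along(area) - 1L, area = area)
  if (!is.null(module)) df$module <- module
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabelsTSV
#' @export
readLabelsTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

# ---- streamline formats -------------------------------------------------

#' Read and write plain-text polyline streamlines
#'
#' One point per line (`x y z`), blank line between streamlines.
#'
#' @param path File path.
#' @param x A [StreamlineSet-class].
#' @return `readPolylines` returns a [StreamlineSet-class].
#' @export
writePolylines <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x@points)) {
    writeLines(apply(x@points[[i]], 1, function(p)
      paste(sprintf("%.17g", p), collapse = " ")), con)
    if (i < length(x@points)) writeLines("", con)
  }
  invisible(path)
}

#' @rdname writePolylines
#' @export
readPolylines <- function(path) {
  lines <- readLines(path)
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank)[!blank]
  lns <- lines[!blank]
  pts <- lapply(split(lns, grp), function(ls) {
    m <- do.call(rbind, lapply(seq_along(ls), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(ls[i]), "\\s+")[[1]]))
      if (length(v) != 3 || any(is.na(v)))
        stop(sprintf("%s: malformed point on polyline line %d", path, i),
             call. = FALSE)
      v
    }))
    dimnames(m) <- NULL
    m
  })
  names(pts) <- NULL
  new("StreamlineSet", points = pts, labels = character(0))
}

#' Read and write TCK (MRtrix track) streamline files
#'
#' Binary TCK with `Float32LE` datatype. Coordinates are stored as 32-bit
#' floats, so a round trip is lossy at float32 precision (documented).
#'
#' @param path File path.
#' @param x A [StreamlineSet-class].
#' @return `readTCK` returns a [StreamlineSet-class].
#' @export
writeTCK <- function(x, path) {
  headerOf <- function(offset)
    paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
           length(x@points), "\nfile: . ", offset, "\nEND\n")
  # fixed-point header size (offset digits may change header length)
  off <- nchar(headerOf(0), type = "bytes")
  repeat {
    off2 <- nchar(headerOf(off), type = "bytes")
    if (off2 == off) break
    off <- off2
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(headerOf(off), con, eos = NULL)
  for (p in x@points) {
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname writeTCK
#' @export
readTCK <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  nbytes <- 0L
  repeat {
    line <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1)
      nbytes <- nbytes + 1L
      if (!length(b) || b == as.raw(10L)) break
      line <- c(line, b)
    }
    header <- c(header, rawToChar(line))
    if (trimws(utils::tail(header, 1)) == "END") break
    if (length(header) > 200)
      stop(sprintf("%s: TCK header not terminated at byte %d", path, nbytes),
           call. = FALSE)
  }
  if (header[1] != "mrtrix tracks")
    stop(sprintf("%s: not a TCK file (bad magic)", path), call. = FALSE)
  fileLine <- header[grepl("^file:", header)]
  offset <- as.integer(strsplit(trimws(fileLine), "\\s+")[[1]][3])
  dt <- sub("^datatype:\\s*", "", header[grepl("^datatype:", header)])
  if (trimws(dt) != "Float32LE")
    stop(sprintf("%s: unsupported TCK datatype %s", path, dt),
         call. = FALSE)
  seek(con, offset)
  vals <- readBin(con, "double", n = file.size(path), size = 4,
                  endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  pts <- list()
  cur <- integer(0)
  for (i in seq_len(nrow(m))) {
    if (all(is.infinite(m[i, ]))) break
    if (all(is.nan(m[i, ]))) {
      if (length(cur)) pts[[length(pts) + 1L]] <- m[cur, , drop = FALSE]
      cur <- integer(0)
    } else cur <- c(cur, i)
  }
  if (length(cur)) pts[[length(pts) + 1L]] <- m[cur, , drop = FALSE]
  new("StreamlineSet", points = pts, labels = character(0))
}

# ---- network formats ----------------------------------------------------

#' Write and read a binary network in MatrixMarket pattern format
#'
#' Symmetric pattern coordinate MatrixMarket (`%%MatrixMarket matrix
#' coordinate pattern symmetric`), 1-based ids as the format prescribes,
#' lower-triangle entries; plus a companion node TSV written by
#' [writeNodeTableTSV()].
#'
#' @param network A [ConnectomeNetwork-class] (write) / file path (read).
#' @param path File path.
#' @param nodes Optional node table for reading.
#' @return `readNetworkMM` returns a [ConnectomeNetwork-class].
#' @export
writeNetworkMM <- function(network, path) {
  g <- asGraph(network)
  el <- igraph::as_edgelist(g, names = FALSE)
  a <- pmax(el[, 1], el[, 2]); b <- pmin(el[, 1], el[, 2])
  o <- order(a, b)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate pattern symmetric", con)
  writeLines(sprintf("%d %d %d", igraph::vcount(g), igraph::vcount(g),
                     nrow(el)), con)
  writeLines(sprintf("%d %d", a[o], b[o]), con)
  invisible(path)
}

#' @rdname writeNetworkMM
#' @export
readNetworkMM <- function(path, nodes = NULL) {
  m <- Matrix::readMM(path)
  m <- methods::as(m, "CsparseMatrix")
  sm <- Matrix::forceSymmetric(m != 0, uplo = "L")
  g <- igraph::graph_from_adjacency_matrix(sm, mode = "undirected",
                                           diag = FALSE)
  if (is.null(nodes))
    nodes <- data.frame(area = rep(NA_character_, igraph::vcount(g)),
                        x = NA_real_, y = NA_real_, z = NA_real_,
                        stringsAsFactors = FALSE)
  new("ConnectomeNetwork", graph = g, nodes = nodes)
}

#' Write and read the node table of a network
#'
#' TSV with columns `triangle_id` (0-based), `area`, `x`, `y`, `z` and
#' optionally `module`.
#'
#' @param network A [ConnectomeNetwork-class].
#' @param path File path.
#' @param module Optional module assignment per node.
#' @return `readNodeTableTSV` returns the data.frame.
#' @export
writeNodeTableTSV <- function(network, path, module = NULL) {
  nd <- network@nodes
  df <- data.frame(triangle_id = seq_len(nrow(nd)) - 1L,
                   area = nd$area,
                   x = sprintf("%.17g", nd$x), y = sprintf("%.17g", nd$y),
                   z = sprintf("%.17g", nd$z))
  if (!is.null(module)) df$module <- module
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeNodeTableTSV
#' @export
readNodeTableTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
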