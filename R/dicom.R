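# Minimal DICOM RT Plan serialization (Explicit VR Little Endian).
#
# Only the subset of the RT Plan IOD that carries dual-layer leaf
# sequences is handled: BeamSequence with BeamLimitingDeviceSequence and
# ControlPointSequence, plus FractionGroupSequence for the beam meterset.
# Layers are identified by pair count (29 -> proximal, 28 -> distal).

.UID_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
.UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.UID_ROOT <- "1.2.826.0.1.3680043.10.1137"
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16le <- function(x) writeBin(as.integer(x), raw(), size = 2,
                               endian = "little")
.u32le <- function(x) writeBin(as.integer(x), raw(), size = 4,
                               endian = "little")

.fmtDS <- function(x) {
  s <- sprintf("%.10g", x)
  if (any(nchar(s) > 16)) stop("DS value too long")
  s
}

.strBody <- function(values, padByte = as.raw(0x20)) {
  b <- charToRaw(paste(values, collapse = "\\"))
  if (length(b) %% 2L == 1L) b <- c(b, padByte)
  b
}

.element <- function(group, elem, vr, body) {
  tag <- c(.u16le(group), .u16le(elem))
  if (vr %in% .LONG_VRS) {
    c(tag, charToRaw(vr), raw(2), .u32le(length(body)), body)
  } else {
    c(tag, charToRaw(vr), .u16le(length(body)), body)
  }
}

.item <- function(body) {
  c(.u16le(0xFFFE), .u16le(0xE000), .u32le(length(body)), body)
}

.sqElement <- function(group, elem, items) {
  .element(group, elem, "SQ", do.call(c, c(list(raw(0)), items)))
}

.deviceType <- function(layerId) {
  c(proximal = "MLCX1", distal = "MLCX2")[[layerId]]
}

.leafBoundaries <- function(spec) {
  w <- spec@leafWidthIso
  n <- spec@nPairs
  seq(-n * w / 2, n * w / 2, by = w)
}

# ---- writer ------------------------------------------------------------

#' Write a plan as a DICOM RT Plan
#'
#' Serializes to Explicit VR Little Endian.  Every leaf position is
#' rounded to the nearest 0.1 mm (ties half-up) -- the serialization
#' resolution of the TPS -- while meterset weights, MU and labels are
#' preserved.  Rounding happens only here, never in-memory.
#'
#' @param plan a valid [DualLayerPlan-class].
#' @param dest optional path to write the byte stream to.
#' @return raw vector of the encoded file (invisibly when `dest` given).
#' @seealso [readPlan()]
#' @export
writePlan <- function(plan, dest = NULL) {
  issues <- validatePlan(plan)
  if (length(issues))
    stop("plan fails validation: ", paste(issues, collapse = "; "))

  beamItems <- list()
  refBeamItems <- list()
  for (bi in seq_along(plan@beams)) {
    beam <- plan@beams[[bi]]
    bldItems <- lapply(c("proximal", "distal"), function(ly) {
      spec <- beam@layerSpecs[[ly]]
      .item(c(
        .element(0x300A, 0x00B8, "CS", .strBody(.deviceType(ly))),
        .element(0x300A, 0x00BC, "IS", .strBody(as.character(spec@nPairs))),
        .element(0x300A, 0x00BE, "DS", .strBody(.fmtDS(.leafBoundaries(spec))))
      ))
    })
    cpItems <- lapply(seq_along(beam@controlPoints), function(ci) {
      cp <- beam@controlPoints[[ci]]
      posItems <- lapply(c("proximal", "distal"), function(ly) {
        spec <- beam@layerSpecs[[ly]]
        p <- roundHalfUp(cp@positions[[ly]], 1)
        if (any(p[, 1] < spec@travelMin - 1e-9 |
                p[, 2] > spec@travelMax + 1e-9))
          stop(sprintf(
            "beam %d cp %d: %s position outside travel range after rounding",
            bi, ci, ly))
        .item(c(
          .element(0x300A, 0x00B8, "CS", .strBody(.deviceType(ly))),
          .element(0x300A, 0x011C, "DS",
                   .strBody(sprintf("%.1f", c(p[, 1], p[, 2]))))
        ))
      })
      .item(c(
        .element(0x300A, 0x0112, "IS", .strBody(as.character(cp@index))),
        .sqElement(0x300A, 0x011A, posItems),
        .element(0x300A, 0x011E, "DS", .strBody(.fmtDS(cp@gantry))),
        .element(0x300A, 0x0134, "DS", .strBody(.fmtDS(cp@weight)))
      ))
    })
    beamItems[[bi]] <- .item(c(
      .sqElement(0x300A, 0x00B6, bldItems),
      .element(0x300A, 0x00C0, "IS", .strBody(as.character(bi))),
      .element(0x300A, 0x00C2, "LO", .strBody(sprintf("Arc%d", bi))),
      .element(0x300A, 0x010E, "DS", .strBody("1")),
      .element(0x300A, 0x0110, "IS",
               .strBody(as.character(length(beam@controlPoints)))),
      .sqElement(0x300A, 0x0111, cpItems)
    ))
    refBeamItems[[bi]] <- .item(c(
      .element(0x300A, 0x0086, "DS", .strBody(.fmtDS(beam@mu))),
      .element(0x300C, 0x0006, "IS", .strBody(as.character(bi)))
    ))
  }

  fgItem <- .item(c(
    .element(0x300A, 0x0071, "IS", .strBody("1")),
    .element(0x300A, 0x0078, "IS", .strBody("1")),
    .element(0x300A, 0x0080, "IS",
             .strBody(as.character(length(plan@beams)))),
    .sqElement(0x300C, 0x0004, refBeamItems)
  ))

  md <- plan@metadata
  label <- if (is.null(md$id)) "dualmlc" else as.character(md$id)
  name <- if (is.null(md$target_class)) "" else as.character(md$target_class)
  uid <- if (!is.null(md$uid)) as.character(md$uid) else {
    # content-derived, deterministic instance UID
    posSum <- sum(vapply(plan@beams, function(b)
      sum(vapply(b@controlPoints,
                 function(cp) sum(abs(unlist(cp@positions))), numeric(1))),
      numeric(1)))
    sprintf("%s.%d.%d", .UID_ROOT,
            as.integer(round(posSum * 10) %% 1e9), length(plan@beams))
  }

  dataset <- c(
    .element(0x0008, 0x0016, "UI", .strBody(.UID_RTPLAN, as.raw(0))),
    .element(0x0008, 0x0018, "UI", .strBody(uid, as.raw(0))),
    .element(0x0008, 0x0060, "CS", .strBody("RTPLAN")),
    .element(0x300A, 0x0002, "SH", .strBody(label)),
    .element(0x300A, 0x0003, "LO", .strBody(name)),
    .sqElement(0x300A, 0x0070, list(fgItem)),
    .sqElement(0x300A, 0x00B0, beamItems)
  )

  metaBody <- c(
    .element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .element(0x0002, 0x0002, "UI", .strBody(.UID_RTPLAN, as.raw(0))),
    .element(0x0002, 0x0003, "UI", .strBody(uid, as.raw(0))),
    .element(0x0002, 0x0010, "UI", .strBody(.UID_EXPLICIT_LE, as.raw(0))),
    .element(0x0002, 0x0012, "UI", .strBody(paste0(.UID_ROOT, ".1"),
                                            as.raw(0)))
  )
  meta <- c(.element(0x0002, 0x0000, "UL", .u32le(length(metaBody))),
            metaBody)

  out <- c(raw(128), charToRaw("DICM"), meta, dataset)
  if (!is.null(dest)) {
    writeBin(out, dest)
    return(invisible(out))
  }
  out
}

# ---- reader ------------------------------------------------------------

.newCursor <- function(r) {
  env <- new.env(parent = emptyenv())
  env$r <- r
  env$pos <- 1L
  env
}

.readU16 <- function(cur) {
  v <- as.integer(cur$r[cur$pos]) + 256L * as.integer(cur$r[cur$pos + 1L])
  cur$pos <- cur$pos + 2L
  v
}

.readU32 <- function(cur) {
  b <- as.numeric(cur$r[cur$pos + 0:3])
  cur$pos <- cur$pos + 4L
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}

.readRaw <- function(cur, n) {
  v <- cur$r[seq.int(cur$pos, length.out = n)]
  cur$pos <- cur$pos + as.integer(n)
  v
}

.peekTag <- function(cur) {
  c(as.integer(cur$r[cur$pos]) + 256L * as.integer(cur$r[cur$pos + 1L]),
    as.integer(cur$r[cur$pos + 2L]) + 256L * as.integer(cur$r[cur$pos + 3L]))
}

.STRING_VRS <- c("UI", "CS", "DS", "IS", "LO", "SH", "PN", "AE", "AS",
                 "DA", "TM", "DT", "LT", "ST", "UT")

.parseValue <- function(vr, body) {
  if (vr %in% .STRING_VRS) {
    s <- rawToChar(body[body != as.raw(0)])
    s <- sub("[ ]+$", "", s)
    strsplit(s, "\\\\")[[1]]
  } else if (vr == "UL") {
    sum(as.numeric(body) * 256^(seq_along(body) - 1))
  } else {
    body
  }
}

.parseItems <- function(cur, len) {
  items <- list()
  endPos <- if (is.finite(len)) cur$pos + len else Inf
  repeat {
    if (cur$pos >= endPos) break
    tag <- .peekTag(cur)
    if (tag[1] == 0xFFFE && tag[2] == 0xE0DD) {  # sequence delimiter
      cur$pos <- cur$pos + 8L
      break
    }
    if (!(tag[1] == 0xFFFE && tag[2] == 0xE000))
      stop("malformed sequence: expected item tag")
    cur$pos <- cur$pos + 4L
    ilen <- .readU32(cur)
    if (ilen == 4294967295) {  # undefined item length
      items[[length(items) + 1L]] <- .parseDataset(cur, Inf, itemLevel = TRUE)
    } else {
      items[[length(items) + 1L]] <- .parseDataset(cur, cur$pos + ilen)
    }
  }
  items
}

.parseDataset <- function(cur, endPos, itemLevel = FALSE) {
  elems <- list()
  repeat {
    if (cur$pos >= endPos || cur$pos > length(cur$r)) break
    tag <- .peekTag(cur)
    if (itemLevel && tag[1] == 0xFFFE && tag[2] == 0xE00D) {
      cur$pos <- cur$pos + 8L
      break
    }
    group <- .readU16(cur)
    elem <- .readU16(cur)
    vr <- rawToChar(.readRaw(cur, 2L))
    if (vr %in% .LONG_VRS) {
      .readRaw(cur, 2L)
      len <- .readU32(cur)
    } else {
      len <- .readU16(cur)
    }
    key <- sprintf("%04X%04X", group, elem)
    if (vr == "SQ") {
      val <- .parseItems(cur, if (len == 4294967295) Inf else len)
    } else {
      if (len == 4294967295) stop("undefined length outside SQ unsupported")
      val <- .parseValue(vr, .readRaw(cur, len))
    }
    elems[[key]] <- list(vr = vr, value = val)
  }
  elems
}

.dsGet <- function(ds, group, elem) {
  e <- ds[[sprintf("%04X%04X", group, elem)]]
  if (is.null(e)) NULL else e$value
}

#' Read a DICOM RT Plan with two MLC layers
#'
#' Parses an Explicit VR Little Endian RT Plan and builds the in-memory
#' plan.  The two MLC beam-limiting devices are identified by pair count
#' (29 pairs is the proximal layer, 28 the distal); anything else is
#' rejected as a geometry error.  Positions are taken as written (mm at
#' isocenter); no rounding is applied on read.
#'
#' @param source path to a file or a raw vector as returned by
#'   [writePlan()].
#' @return a [DualLayerPlan-class].
#' @export
readPlan <- function(source) {
  r <- if (is.raw(source)) source else
    readBin(source, "raw", file.size(source))
  if (length(r) < 132 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM part-10 file")
  cur <- .newCursor(r)
  cur$pos <- 133L
  # file meta group
  repeat {
    tag <- .peekTag(cur)
    if (tag[1] != 0x0002) break
    group <- .readU16(cur); elem <- .readU16(cur)
    vr <- rawToChar(.readRaw(cur, 2L))
    len <- if (vr %in% .LONG_VRS) { .readRaw(cur, 2L); .readU32(cur) } else
      .readU16(cur)
    val <- .parseValue(vr, .readRaw(cur, len))
    if (group == 0x0002 && elem == 0x0010 &&
        !identical(val, .UID_EXPLICIT_LE))
      stop("unsupported transfer syntax: ", val)
  }
  ds <- .parseDataset(cur, length(r) + 1L)

  beamItems <- .dsGet(ds, 0x300A, 0x00B0)
  if (is.null(beamItems) || !length(beamItems))
    stop("no BeamSequence in RT Plan")

  # beam meterset lookup
  mus <- list()
  fg <- .dsGet(ds, 0x300A, 0x0070)
  if (!is.null(fg) && length(fg)) {
    for (rb in (.dsGet(fg[[1]], 0x300C, 0x0004) %||% list())) {
      num <- as.integer(.dsGet(rb, 0x300C, 0x0006))
      mus[[as.character(num)]] <- as.numeric(.dsGet(rb, 0x300A, 0x0086))
    }
  }

  beamsOut <- list()
  for (bIt in beamItems) {
    bld <- .dsGet(bIt, 0x300A, 0x00B6) %||% list()
    devs <- lapply(bld, function(it) list(
      type = .dsGet(it, 0x300A, 0x00B8),
      nPairs = as.integer(.dsGet(it, 0x300A, 0x00BC))))
    mlc <- Filter(function(d) isTRUE(d$nPairs > 1L), devs)
    if (length(mlc) < 2L)
      stop("single-layer plan: found ", length(mlc),
           " MLC device(s), need two layers")
    counts <- vapply(mlc, function(d) d$nPairs, integer(1))
    if (!setequal(counts, c(28L, 29L)) || length(counts) != 2L)
      stop("geometry error: expected 29 + 28 leaf pairs, found ",
           paste(counts, collapse = " + "))
    typeOf <- c(proximal = mlc[[which(counts == 29L)]]$type,
                distal = mlc[[which(counts == 28L)]]$type)
    specs <- halcyonLayerSpecs()

    cpItems <- .dsGet(bIt, 0x300A, 0x0111) %||% list()
    gantry <- 0
    cps <- list()
    for (k in seq_along(cpItems)) {
      it <- cpItems[[k]]
      g <- .dsGet(it, 0x300A, 0x011E)
      if (!is.null(g)) gantry <- as.numeric(g)
      w <- as.numeric(.dsGet(it, 0x300A, 0x0134))
      posItems <- .dsGet(it, 0x300A, 0x011A) %||% list()
      pos <- list()
      for (pIt in posItems) {
        ty <- .dsGet(pIt, 0x300A, 0x00B8)
        ly <- names(typeOf)[match(ty, typeOf)]
        if (is.na(ly)) next
        v <- as.numeric(.dsGet(pIt, 0x300A, 0x011C))
        n <- length(v) / 2L
        if (n != specs[[ly]]@nPairs)
          stop("geometry error: ", ly, " positions carry ", n,
               " pairs, expected ", specs[[ly]]@nPairs)
        pos[[ly]] <- cbind(A = v[seq_len(n)], B = v[n + seq_len(n)])
      }
      idx <- as.integer(.dsGet(it, 0x300A, 0x0112) %||% (k - 1L))
      cps[[k]] <- ControlPoint(idx, w, gantry, pos)
    }
    w <- vapply(cps, function(cp) cp@weight, numeric(1))
    if (any(diff(w) < -1e-9))
      stop("validation error: cumulative meterset weight decreases")
    num <- as.integer(.dsGet(bIt, 0x300A, 0x00C0) %||% (length(beamsOut) + 1L))
    mu <- mus[[as.character(num)]] %||% 100
    beamsOut[[length(beamsOut) + 1L]] <- Beam(mu, cps, specs)
  }

  md <- list()
  lab <- .dsGet(ds, 0x300A, 0x0002)
  if (!is.null(lab) && length(lab)) md$id <- lab
  nm <- .dsGet(ds, 0x300A, 0x0003)
  if (!is.null(nm) && length(nm)) md$target_class <- nm
  uid <- .dsGet(ds, 0x0008, 0x0018)
  if (!is.null(uid)) md$uid <- uid

  plan <- DualLayerPlan(beamsOut, metadata = md)
  issues <- validatePlan(plan)
  if (length(issues))
    stop("validation error: ", paste(issues, collapse = "; "))
  plan
}

`%||%` <- function(a, b) if (is.null(a)) b else a
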