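#' The nine aneurysm-wall tissue texture classes
#'
#' Returns the registry of tissue texture classes used to segment H&E-stained
#' aneurysm wall sections, together with the display colors used in label
#' images. Classes 1-9 are tissue; two auxiliary labels mark the lumen
#' (inner region, 10) and, optionally, the exterior (11) in normalized
#' label rasters. Label 0 is background.
#'
#' @return data frame with columns `id`, `name`, `r`, `g`, `b` (display
#'   color, 0-255).
#' @examples
#' tissue_classes()
#' @export
tissue_classes <- function() {
  data.frame(
    id = 1:9,
    name = c(
      "mixed textures",
      "inflammatory cells",
      "myointimal hyperplasia",
      "degenerated wall",
      "decellularized OT/MH",
      "red thrombus",
      "organizing thrombus",
      "white thrombus",
      "intact wall"
    ),
    r = c(128L, 255L,   0L,   0L, 255L, 255L, 139L, 255L, 128L),
    g = c(128L, 165L,   0L, 128L, 192L,   0L,  69L, 255L,   0L),
    b = c(128L,   0L, 255L,   0L, 203L,   0L,  19L,   0L, 128L),
    stringsAsFactors = FALSE
  )
}

#' Color palette mapping label-image colors to class ids
#'
#' The palette is a bijection between display colors and label values:
#' classes 1-9 (gray, orange, blue, green, pink, red, brown, yellow,
#' purple - following the conventions of segmented section figures),
#' background 0 (black), lumen marker 10 (white) and exterior marker 11
#' (dark gray). It round-trips exactly with the label-image reader/writer.
#'
#' @return data frame with columns `id`, `r`, `g`, `b`.
#' @seealso [read_label_slice()], [write_label_slice()]
#' @export
class_palette <- function() {
  tc <- tissue_classes()
  rbind(
    data.frame(id = 0L,  r = 0L,   g = 0L,   b = 0L),
    tc[, c("id", "r", "g", "b")],
    data.frame(id = c(10L, 11L), r = c(255L, 64L), g = c(255L, 64L),
               b = c(255L, 64L))
  )
}

# internal: rgb triple -> single comparable key
.rgb_key <- function(r, g, b) r * 65536L + g * 256L + b

#' Convert an RGB color array to a label raster via the palette
#'
#' @param rgb numeric array `h x w x 3` with channels in 0-255 (integers).
#' @param palette data frame as returned by [class_palette()].
#' @return integer label matrix `h x w`.
#' @export
palette_to_labels <- function(rgb, palette = class_palette()) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] >= 3L)
  key <- .rgb_key(round(rgb[, , 1]), round(rgb[, , 2]), round(rgb[, , 3]))
  pkey <- .rgb_key(palette$r, palette$g, palette$b)
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    bad_txt <- vapply(bad, function(k) {
      sprintf("rgb(%d,%d,%d)", k %/% 65536L, (k %/% 256L) %% 256L, k %% 256L)
    }, character(1))
    stop(sprintf(
      "found %d pixel(s) with %d color(s) not in the palette: %s",
      sum(is.na(idx)), length(bad), paste(bad_txt, collapse = ", ")
    ), call. = FALSE)
  }
  matrix(palette$id[idx], nrow = dim(rgb)[1], ncol = dim(rgb)[2])
}

#' Convert a label raster to an RGB color array via the palette
#'
#' @param labels integer label matrix.
#' @param palette data frame as returned by [class_palette()].
#' @return numeric array `h x w x 3` with channels in 0-255.
#' @export
labels_to_palette <- function(labels, palette = class_palette()) {
  idx <- match(labels, palette$id)
  if (anyNA(idx)) {
    stop(sprintf("label value(s) %s not in the palette",
                 paste(unique(labels[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  out <- array(0, dim = c(nrow(labels), ncol(labels), 3))
  out[, , 1] <- palette$r[idx]
  out[, , 2] <- palette$g[idx]
  out[, , 3] <- palette$b[idx]
  out
}

#' Derive the per-class elastic material table
#'
#' Builds the table of Young's moduli for the tissue classes from the two
#' literature values - white thrombus (class 8) and intact wall (class 9) -
#' using fixed texture-based combination rules for the classes without
#' literature data:
#' class 1 (mixed textures) is the average of classes 8 and 9;
#' class 3 (myointimal hyperplasia) is 1/4 of class 8 plus 3/4 of class 9;
#' class 5 (decellularized OT/MH) is the average of classes 3 and 8;
#' class 6 (red thrombus) is half of class 8.
#' Classes 2, 4 and 7 carry no rule and are only included when supplied
#' explicitly via `extra`; a model containing such a class without an
#' explicit modulus aborts (guessing stiffness would corrupt simulations).
#' Values are stored at full precision; printed tables round to two decimals
#' for display only.
#'
#' @param E_white_thrombus Young's modulus of white thrombus (class 8), kPa.
#' @param E_intact_wall Young's modulus of intact wall (class 9), kPa.
#' @param poisson Poisson ratio applied to every class (default 0.45).
#' @param extra optional named numeric vector/list of moduli (kPa) for
#'   classes absent from the rules, e.g. `c("2" = 50)`.
#' @param default_class class assigned to wall volume not covered by any
#'   tissue mesh; defaults to 9 (intact wall), matching the homogeneous
#'   reference configuration.
#' @return object of class `material_table`: data frame with columns
#'   `class_id`, `name`, `modulus_kPa`, `poisson`, `provenance`, plus a
#'   `default_class` attribute.
#' @examples
#' mt <- derive_material_table(36.44, 133.9)
#' mt
#' @export
derive_material_table <- function(E_white_thrombus, E_intact_wall,
                                  poisson = 0.45, extra = NULL,
                                  default_class = 9L) {
  check_that(is_number(E_white_thrombus) && E_white_thrombus > 0,
             "E_white_thrombus", "must be a positive number (kPa)")
  check_that(is_number(E_intact_wall) && E_intact_wall > 0,
             "E_intact_wall", "must be a positive number (kPa)")
  check_that(is_number(poisson) && poisson > 0 && poisson < 0.5,
             "poisson", "must lie strictly in (0, 0.5)")
  E8 <- E_white_thrombus
  E9 <- E_intact_wall
  E1 <- (E8 + E9) / 2
  E3 <- E8 / 4 + 3 * E9 / 4
  E5 <- (E3 + E8) / 2
  E6 <- E8 / 2
  ids <- c(1L, 3L, 5L, 6L, 8L, 9L)
  mod <- c(E1, E3, E5, E6, E8, E9)
  prov <- c("derived-by-rule", "derived-by-rule", "derived-by-rule",
            "derived-by-rule", "literature", "literature")
  if (!is.null(extra)) {
    extra <- unlist(extra)
    eid <- as.integer(names(extra))
    check_that(!anyNA(eid) && all(eid %in% 1:9),
               "extra", "names must be tissue class ids 1-9")
    check_that(all(extra > 0), "extra", "moduli must be positive (kPa)")
    keep <- !(ids %in% eid)
    ids <- c(ids[keep], eid)
    mod <- c(mod[keep], as.numeric(extra))
    prov <- c(prov[keep], rep("config", length(eid)))
    ord <- order(ids)
    ids <- ids[ord]; mod <- mod[ord]; prov <- prov[ord]
  }
  check_that(is_number(default_class) && default_class %in% ids,
             "default_class", "must be a class present in the table")
  tc <- tissue_classes()
  out <- data.frame(
    class_id = ids,
    name = tc$name[match(ids, tc$id)],
    modulus_kPa = mod,
    poisson = rep(poisson, length(ids)),
    provenance = prov,
    stringsAsFactors = FALSE
  )
  attr(out, "default_class") <- as.integer(default_class)
  class(out) <- c("material_table", "data.frame")
  out
}

#' @export
print.material_table <- function(x, ...) {
  cat("Tissue material table (", nrow(x), " classes, default class ",
      attr(x, "default_class"), ")\n", sep = "")
  shown <- as.data.frame(x)
  shown$modulus_kPa <- round(shown$modulus_kPa, 2)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Look up the elastic constants of one tissue class
#'
#' @param materials a [derive_material_table()] result.
#' @param class_id tissue class id.
#' @return list with `modulus_kPa` and `poisson`.
#' @export
material_for_class <- function(materials, class_id) {
  i <- match(class_id, materials$class_id)
  if (is.na(i)) {
    stop(sprintf(
      paste0("tissue class %d has no material: supply its Young's modulus ",
             "explicitly (classes 2, 4 and 7 have no derivation rule)"),
      class_id), call. = FALSE)
  }
  list(modulus_kPa = materials$modulus_kPa[i], poisson = materials$poisson[i])
}

#' Write a material table to a flat config file
#'
#' One section per class with keys `name`, `modulus_kPa`, `poisson`,
#' `provenance`; full numeric precision (round-trips exactly).
#'
#' @param materials a `material_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_materials_config <- function(materials, path) {
  cfg <- list(default_class = attr(materials, "default_class"))
  for (i in seq_len(nrow(materials))) {
    cfg[[sprintf("class_%d", materials$class_id[i])]] <- list(
      name = materials$name[i],
      modulus_kPa = materials$modulus_kPa[i],
      poisson = materials$poisson[i],
      provenance = materials$provenance[i]
    )
  }
  write_flat_config(cfg, path)
}

#' Read a material table from a flat config file
#'
#' @param path file written by [write_materials_config()].
#' @return a `material_table`.
#' @export
read_materials_config <- function(path) {
  cfg <- read_flat_config(path)
  secs <- cfg[grepl("^class_[0-9]+$", names(cfg))]
  check_that(length(secs) > 0, "path", "no [class_*] sections found")
  ids <- as.integer(sub("^class_", "", names(secs)))
  ord <- order(ids)
  out <- data.frame(
    class_id = ids[ord],
    name = vapply(secs[ord], function(s) as.character(s$name), character(1)),
    modulus_kPa = vapply(secs[ord], function(s) as.numeric(s$modulus_kPa),
                         numeric(1)),
    poisson = vapply(secs[ord], function(s) as.numeric(s$poisson), numeric(1)),
    provenance = vapply(secs[ord], function(s) as.character(s$provenance),
                        character(1)),
    stringsAsFactors = FALSE
  )
  check_that(all(out$modulus_kPa > 0), "modulus_kPa", "must all be positive")
  check_that(all(out$poisson > 0 & out$poisson < 0.5), "poisson",
             "must all lie in (0, 0.5)")
  attr(out, "default_class") <- as.integer(cfg$default_class %||% 9L)
  class(out) <- c("material_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
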