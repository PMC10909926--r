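## Item registry: binds each of the 30 automatable FMA-UE items to its
## motions, feature recipe and fuzzy inference system(s); plus the total
## score and hemiplegia severity classification.

angle_sub <- function(motion, label) list(motion = motion, label = label)

ITEM_TABLE <- list(
  list(id = 3L,  sym = "F1",  name = "Shoulder elevation", kind = "angle",
       subs = list(angle_sub("M1", "shoulder_elevation"))),
  list(id = 4L,  sym = "F2",  name = "Shoulder retraction", kind = "angle",
       subs = list(angle_sub("M1", "shoulder_retraction"))),
  list(id = 5L,  sym = "F3",  name = "Shoulder abduction", kind = "angle",
       subs = list(angle_sub("M1", "shoulder_abduction"))),
  list(id = 6L,  sym = "F4",  name = "Shoulder external rotation", kind = "angle",
       subs = list(angle_sub("M1", "shoulder_rotation"))),
  list(id = 7L,  sym = "F5",  name = "Elbow flexion", kind = "angle",
       subs = list(angle_sub("M1", "elbow_flexion"))),
  list(id = 8L,  sym = "F6",  name = "Forearm supination", kind = "angle",
       subs = list(angle_sub("M1", "forearm_pronation"))),
  list(id = 9L,  sym = "F7",  name = "Shoulder adduction/internal rotation",
       kind = "angle", subs = list(angle_sub("M2", "shoulder_rotation"))),
  list(id = 10L, sym = "F8",  name = "Elbow extension", kind = "angle",
       subs = list(angle_sub("M2", "elbow_flexion"))),
  list(id = 11L, sym = "F9",  name = "Forearm pronation", kind = "angle",
       subs = list(angle_sub("M2", "forearm_pronation"))),
  list(id = 12L, sym = "F10", name = "Hand to lumbar spine", kind = "alpha",
       subs = list(list(motion = "M3"))),
  list(id = 13L, sym = "F11", name = "Shoulder flexion 0-90, elbow extended",
       kind = "angle",
       subs = list(angle_sub("M4", "shoulder_flexion"),
                   angle_sub("M5", "elbow_flexion"))),
  list(id = 14L, sym = "F12", name = "Forearm rotation, elbow 90, shoulder 0",
       kind = "angle",
       subs = list(angle_sub("M6", "forearm_pronation"),
                   angle_sub("M7", "elbow_flexion"),
                   angle_sub("M8", "shoulder_abduction"))),
  list(id = 15L, sym = "F13", name = "Shoulder abduction 0-90, elbow extended",
       kind = "angle",
       subs = list(angle_sub("M9", "shoulder_abduction"),
                   angle_sub("M5", "elbow_flexion"),
                   angle_sub("M6", "forearm_pronation"))),
  list(id = 16L, sym = "F14", name = "Shoulder flexion 90-180", kind = "angle",
       subs = list(angle_sub("M10", "shoulder_flexion"),
                   angle_sub("M5", "elbow_flexion"))),
  list(id = 17L, sym = "F15", name = "Forearm rotation, elbow extended",
       kind = "angle",
       subs = list(angle_sub("M5", "elbow_flexion"),
                   angle_sub("M6", "forearm_pronation"),
                   angle_sub("M11", "shoulder_flexion"))),
  list(id = 19L, sym = "F16", name = "Wrist stability, elbow 90", kind = "angle",
       subs = list(angle_sub("M12", "wrist_flexion"),
                   angle_sub("M7", "elbow_flexion"),
                   angle_sub("M8", "shoulder_abduction"))),
  list(id = 20L, sym = "F17", name = "Wrist flexion-extension, elbow 90",
       kind = "angle",
       subs = list(angle_sub("M13", "wrist_flexion"),
                   angle_sub("M7", "elbow_flexion"))),
  list(id = 21L, sym = "F18", name = "Wrist stability, elbow 0, shoulder 30",
       kind = "angle",
       subs = list(angle_sub("M12", "wrist_flexion"),
                   angle_sub("M5", "elbow_flexion"),
                   angle_sub("M11", "shoulder_flexion"))),
  list(id = 22L, sym = "F19", name = "Wrist flexion-extension, elbow 0",
       kind = "angle",
       subs = list(angle_sub("M12", "wrist_flexion"),
                   angle_sub("M5", "elbow_flexion"),
                   angle_sub("M11", "shoulder_flexion"))),
  list(id = 23L, sym = "F20", name = "Wrist circumduction", kind = "angle",
       subs = list(angle_sub("M13", "wrist_flexion"),
                   angle_sub("M5", "elbow_flexion"),
                   angle_sub("M11", "shoulder_flexion"))),
  list(id = 24L, sym = "F21", name = "Mass flexion", kind = "finger",
       subs = list(list(motion = "M14", part = "thumb"),
                   list(motion = "M14", part = "four"))),
  list(id = 25L, sym = "F22", name = "Mass extension", kind = "finger",
       subs = list(list(motion = "M15", part = "thumb"),
                   list(motion = "M15", part = "four"))),
  list(id = 26L, sym = "F23", name = "Hook grasp", kind = "force",
       subs = list(list(motion = "M16"))),
  list(id = 27L, sym = "F24", name = "Lateral pinch", kind = "force",
       subs = list(list(motion = "M17"))),
  list(id = 28L, sym = "F25", name = "Pincer grasp", kind = "force",
       subs = list(list(motion = "M18"))),
  list(id = 29L, sym = "F26", name = "Cylinder grasp", kind = "force",
       subs = list(list(motion = "M19"))),
  list(id = 30L, sym = "F27", name = "Sphere grasp", kind = "force",
       subs = list(list(motion = "M20"))),
  list(id = 31L, sym = "F28", name = "Finger-nose tremor", kind = "tremor",
       subs = list(list(motion = "M21"))),
  list(id = 32L, sym = "F29", name = "Finger-nose dysmetria", kind = "dysmetria",
       subs = list(list(motion = "M21"))),
  list(id = 33L, sym = "F30", name = "Finger-nose speed", kind = "speed",
       subs = list(list(motion = "M21")))
)

fis_recipe <- function(kind) {
  switch(kind,
    angle = list(names = c("rom_ratio", "mv_ratio", "sd"),
                 directions = c("increasing", "increasing", "decreasing")),
    alpha = list(names = "reach_ratio", directions = "increasing"),
    finger = list(names = c("angle_ratio", "mv_ratio"),
                  directions = c("increasing", "increasing")),
    force = list(names = "force_ratio", directions = "increasing"),
    tremor = list(names = c("mv_ratio", "ma_sym"),
                  directions = c("increasing", "increasing")),
    dysmetria = list(names = c("beta_sym", "gamma_ratio"),
                     directions = c("increasing", "increasing")),
    speed = list(names = "vmax_ratio", directions = "increasing")
  )
}

#' Build the 30-item scoring registry
#'
#' One entry per automatable FMA-UE item (items 3-17 and 19-33; the two
#' reflex items need a reflex hammer and are out of scope). Each entry
#' carries the motion composition, the feature recipe and one fuzzy
#' inference system per sub-motion. Together the items reference 21
#' distinct motion codes.
#'
#' @param overrides optional named list: `item id -> list of fis_spec`
#'   replacing that item's per-sub-motion FIS list.
#' @return List of item specifications (class `fma_registry`).
#' @export
build_registry <- function(overrides = NULL) {
  items <- lapply(ITEM_TABLE, function(it) {
    rec <- fis_recipe(it$kind)
    it$fis <- replicate(length(it$subs),
                        fis_spec(rec$names, rec$directions),
                        simplify = FALSE)
    it
  })
  names(items) <- vapply(items, function(it) as.character(it$id), "")
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% names(items)) {
        stop_autofma("override names unknown item '%s'", nm,
                     class = "autofma_config_error")
      }
      ov <- overrides[[nm]]
      if (length(ov) != length(items[[nm]]$subs)) {
        stop_autofma("item %s needs %d FIS specs, got %d",
                     nm, length(items[[nm]]$subs), length(ov),
                     class = "autofma_config_error")
      }
      items[[nm]]$fis <- ov
    }
  }
  structure(items, class = "fma_registry")
}

#' Dump the registry as a data.frame (item/motion/feature mapping)
#'
#' @param registry a [build_registry()] result.
#' @return data.frame with one row per sub-motion.
#' @export
registry_table <- function(registry = build_registry()) {
  rows <- do.call(rbind, lapply(registry, function(it) {
    data.frame(item_id = it$id, feature_symbol = it$sym, item = it$name,
               kind = it$kind,
               motion = vapply(it$subs, `[[`, "", "motion"),
               detail = vapply(it$subs, function(s) {
                 if (!is.null(s$label)) s$label
                 else if (!is.null(s$part)) s$part
                 else ""
               }, ""),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Score one item from its per-sub-motion features
#'
#' Each sub-motion's inputs run through that sub-motion's Mamdani FIS and
#' are discretised to {0, 1, 2}; multi-sub-motion items are then combined
#' with [combine_subscores()].
#'
#' @param item one entry of [build_registry()].
#' @param features output of [item_features()] for that item.
#' @return List with `value` (final integer score), `sub_scores`,
#'   `crisp` (per-sub-motion crisp scores).
#' @export
score_item <- function(item, features) {
  if (length(features) != length(item$fis)) {
    stop_autofma("item %d expects %d sub-motion feature sets, got %d",
                 item$id, length(item$fis), length(features),
                 class = "autofma_config_error")
  }
  crisp <- numeric(length(features))
  subs <- integer(length(features))
  for (j in seq_along(features)) {
    res <- mamdani_score(item$fis[[j]], as.list(features[[j]]$inputs))
    crisp[j] <- res$crisp
    subs[j] <- discretise(res$crisp)
  }
  list(value = combine_subscores(subs), sub_scores = subs, crisp = crisp)
}

#' Severity thresholds of the FMA-UE scale
#'
#' Totals below 32 are severe, 32-57 moderate, 58-66 mild hemiplegia.
#'
#' @param severe_below,moderate_upper,mild_upper integer boundaries.
#' @return A `severity_thresholds` list.
#' @export
severity_thresholds <- function(severe_below = 32, moderate_upper = 57,
                                mild_upper = 66) {
  if (!(severe_below <= moderate_upper && moderate_upper <= mild_upper)) {
    stop_autofma("severity thresholds must be non-decreasing",
                 class = "autofma_parameter_error")
  }
  structure(list(severe_below = severe_below, moderate_upper = moderate_upper,
                 mild_upper = mild_upper), class = "severity_thresholds")
}

#' Classify hemiplegia severity from a total score
#'
#' @param total integer total score in `[0, 66]`.
#' @param thresholds a [severity_thresholds()].
#' @return `"severe"`, `"moderate"` or `"mild"`.
#' @export
classify_severity <- function(total, thresholds = severity_thresholds()) {
  if (!is.finite(total) || total < 0 || total > thresholds$mild_upper) {
    stop_autofma("total %s outside [0, %d]", format(total), thresholds$mild_upper,
                 class = "autofma_parameter_error")
  }
  if (total < thresholds$severe_below) "severe"
  else if (total <= thresholds$moderate_upper) "moderate"
  else "mild"
}

#' Run the full assessment pipeline on a recording
#'
#' Filter -> kinematics -> features -> per-item fuzzy scoring -> total and
#' severity. Items whose features cannot be computed (missing clips,
#' uninformative healthy reference) are reported as unscorable and excluded
#' from the total with an explicit diagnostic; they never silently change
#' the total.
#'
#' The severity thresholds are printed for the 66-point clinical scale
#' while the automated total spans 30 items (0-60); by default the raw
#' total is classified with this caveat recorded in the report, or set
#' `rescale66 = TRUE` in the config to classify `total * 66/60`.
#'
#' @param rec a [fma_recording()].
#' @param config an [assess_config()].
#' @param registry a [build_registry()] result.
#' @return An `fma_report`: per-item scores and audit features, `total`,
#'   `severity`, diagnostics.
#' @export
assess <- function(rec, config = assess_config(), registry = build_registry()) {
  rec <- canonicalise_recording(rec)
  items <- list()
  unscored <- list()
  total <- 0L
  for (it in registry) {
    res <- tryCatch({
      feats <- item_features(rec, it, config)
      sc <- score_item(it, feats)
      list(ok = TRUE, feats = feats, sc = sc)
    }, autofma_error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    if (res$ok) {
      total <- total + res$sc$value
      items[[as.character(it$id)]] <- list(
        item_id = it$id, item = it$name, feature_symbol = it$sym,
        score = res$sc$value, sub_scores = res$sc$sub_scores,
        crisp = res$sc$crisp,
        features = lapply(res$feats, function(f) as.list(f$inputs))
      )
    } else {
      unscored[[as.character(it$id)]] <- list(
        item_id = it$id, item = it$name, reason = res$msg)
    }
  }
  sev_total <- if (isTRUE(config$rescale66)) round(total * 66 / 60) else total
  structure(list(
    subject_id = rec$subject_id,
    affected_side = rec$affected_side,
    item_scores = items,
    total = total,
    severity_scale_total = sev_total,
    severity = classify_severity(sev_total),
    severity_caveat = paste(
      "severity thresholds refer to the 66-point clinical scale;",
      "the automated total spans the 30 automatable items (0-60)"),
    unscored = unscored
  ), class = "fma_report")
}

#' @export
print.fma_report <- function(x, ...) {
  cat(sprintf("<fma_report> subject %s (affected side: %s)\n",
              x$subject_id, x$affected_side))
  cat(sprintf("  total %d/60 across %d scored items -> %s hemiplegia\n",
              x$total, length(x$item_scores), x$severity))
  if (length(x$unscored)) {
    cat(sprintf("  %d item(s) unscorable:\n", length(x$unscored)))
    for (u in x$unscored) cat(sprintf("    item %d: %s\n", u$item_id, u$reason))
  }
  invisible(x)
}
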