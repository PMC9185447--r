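#' The 20-class activity and fall taxonomy
#'
#' Returns the fixed taxonomy used throughout the pipeline: 8 periodic
#' activities / static postures, 8 postural transitions and 4 fall types.
#' Class identifiers are the integers 1 to 20 in the order returned.
#'
#' @return A data frame with columns `class_id` (integer 1..20), `name`
#'   (snake_case label) and `category` (one of `"periodic_static"`,
#'   `"transition"`, `"fall"`).
#' @examples
#' tax <- class_taxonomy()
#' table(tax$category)
#' @export
class_taxonomy <- function() {
  data.frame(
    class_id = 1:20,
    name = c(
      "walking", "standing", "sitting", "lying",
      "upstairs", "downstairs", "jumping", "jogging",
      "lying_to_stand", "stand_to_sit", "sit_to_stand",
      "stand_to_pick_to_stand", "stand_to_lying",
      "change_position_lying", "turning", "bending",
      "fall_forwards", "fall_backwards", "fall_lateral", "fall_syncope"
    ),
    category = c(
      rep("periodic_static", 8L),
      rep("transition", 8L),
      rep("fall", 4L)
    ),
    stringsAsFactors = FALSE
  )
}

#' Look up taxonomy class ids by name
#'
#' @param names Character vector of taxonomy names.
#' @return Integer class ids.
#' @export
class_id <- function(names) {
  tax <- class_taxonomy()
  idx <- match(names, tax$name)
  if (anyNA(idx)) {
    abort_contract("unknown class name(s): ",
                   paste(names[is.na(idx)], collapse = ", "))
  }
  tax$class_id[idx]
}

#' Which classes are falls?
#'
#' @param class_ids Integer class ids.
#' @return Logical vector, `TRUE` for the four fall classes.
#' @export
is_fall_class <- function(class_ids) {
  tax <- class_taxonomy()
  if (!all(class_ids %in% tax$class_id)) {
    abort_contract("class ids must be in 1..20")
  }
  tax$category[match(class_ids, tax$class_id)] == "fall"
}
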