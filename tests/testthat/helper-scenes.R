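# shared fixtures built in code

default_intr <- function() camera_intrinsics(600, 600, 320, 240, 640, 480)

small_intr <- function() camera_intrinsics(300, 300, 160, 120, 320, 240)

# a single reference ball on the optical axis, no backdrop
ball_frame <- function(diameter, distance, intr = default_intr()) {
  render_frame(sphere(c(0, 0, distance), diameter / 2), intr)
}

# one stem (optionally inclined, degrees) in front of a backdrop plane
stem_frame <- function(distance, incline_deg = 0, radius = 4,
                       intr = default_intr()) {
  th <- incline_deg * pi / 180
  render_frame(list(
    cylinder(c(-250 * sin(th), -250 * cos(th), distance),
             c(sin(th), cos(th), 0), radius, 500),
    plane(c(0, 0, distance + 1000))), intr)
}

# filled disc mask (1-based center row/col, 0-based pixel semantics follow
# the package convention: pixel (x, y) is matrix cell [y + 1, x + 1])
disc_mask <- function(h, w, cx, cy, r) {
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}
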