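# Shared fixtures, built once per test run and cached. Phantom sizes are
# chosen for test speed; the methods vignette records the problem sizes
# behind each check.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## A mid-density phantom plus its alignment and semilandmarks.
standardPhantom <- function() fixture("standardPhantom", function() {
  ph <- generateBone(bonePhantomParams(nPoints = 8000, seed = 42))
  al <- alignBaculum(ph)
  list(cloud = ph, aligned = al, lms = extractSemilandmarks(al))
})

## Parental phantom parameter sets: a curved, strongly tapered bone versus
## a straight, blunter one (the two parental extremes).
parentParams <- function(n = 20000) {
  list(p1 = bonePhantomParams(nPoints = n, curvature = 0.35, taperTip = 0.45),
       p2 = bonePhantomParams(nPoints = n, curvature = 0.05, taperTip = 0.65))
}

phantomLandmarks <- function(pp, seed, id, config = pipelineConfig()) {
  pp$seed <- seed
  pp$specimenId <- id
  extractSemilandmarks(alignBaculum(generateBone(pp)), config)
}

## Dense ring in the x-y plane at a fixed z: a closed-form slice band.
ringBand <- function(r = 1, n = 5000, z = 0.5) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(r * cos(th), r * sin(th), z)
}

## Random small landmark configuration.
randomConfig <- function(k, seed) {
  set.seed(seed)
  matrix(rnorm(3 * k), k, 3)
}

randomRigid <- function(seed) {
  set.seed(seed)
  R <- bacumorph:::randomRotation()
  list(R = R, t = runif(3, -5, 5))
}
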