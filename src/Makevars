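# Use FFTW3 (present in the build environment) for Armadillo's FFT backend:
# the SPOM step loop spends most of its time in 2D convolutions.
PKG_CPPFLAGS = -DARMA_USE_FFTW3
PKG_LIBS = -lfftw3
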