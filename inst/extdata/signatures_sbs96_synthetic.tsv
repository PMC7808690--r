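channel	SBS1_like	SBS5_like	SBS7b_like	SBS18_like
A[C>A]A	0.002032520325	0.009191176471	0.001482213439	0.0493697479
A[C>A]C	0.002032520325	0.009803921569	0.001482213439	0.0493697479
A[C>A]G	0.002032520325	0.01041666667	0.001482213439	0.0493697479
A[C>A]T	0.002032520325	0.01102941176	0.001482213439	0.0493697479
C[C>A]A	0.002032520325	0.01164215686	0.001482213439	0.0493697479
C[C>A]C	0.002032520325	0.01225490196	0.001482213439	0.0493697479
C[C>A]G	0.002032520325	0.008578431373	0.001482213439	0.0493697479
C[C>A]T	0.002032520325	0.009191176471	0.001482213439	0.0493697479
G[C>A]A	0.002032520325	0.009803921569	0.001482213439	0.0493697479
G[C>A]C	0.002032520325	0.01041666667	0.001482213439	0.0493697479
G[C>A]G	0.002032520325	0.01102941176	0.001482213439	0.0493697479
G[C>A]T	0.002032520325	0.01164215686	0.001482213439	0.0493697479
T[C>A]A	0.002032520325	0.01225490196	0.001482213439	0.0493697479
T[C>A]C	0.002032520325	0.008578431373	0.001482213439	0.0493697479
T[C>A]G	0.002032520325	0.009191176471	0.001482213439	0.0493697479
T[C>A]T	0.002032520325	0.009803921569	0.001482213439	0.0493697479
A[C>G]A	0.002032520325	0.01041666667	0.001482213439	0.00262605042
A[C>G]C	0.002032520325	0.01102941176	0.001482213439	0.00262605042
A[C>G]G	0.002032520325	0.01164215686	0.001482213439	0.00262605042
A[C>G]T	0.002032520325	0.01225490196	0.001482213439	0.00262605042
C[C>G]A	0.002032520325	0.008578431373	0.001482213439	0.00262605042
C[C>G]C	0.002032520325	0.009191176471	0.001482213439	0.00262605042
C[C>G]G	0.002032520325	0.009803921569	0.001482213439	0.00262605042
C[C>G]T	0.002032520325	0.01041666667	0.001482213439	0.00262605042
G[C>G]A	0.002032520325	0.01102941176	0.001482213439	0.00262605042
G[C>G]C	0.002032520325	0.01164215686	0.001482213439	0.00262605042
G[C>G]G	0.002032520325	0.01225490196	0.001482213439	0.00262605042
G[C>G]T	0.002032520325	0.008578431373	0.001482213439	0.00262605042
T[C>G]A	0.002032520325	0.009191176471	0.001482213439	0.00262605042
T[C>G]C	0.002032520325	0.009803921569	0.001482213439	0.00262605042
T[C>G]G	0.002032520325	0.01041666667	0.001482213439	0.00262605042
T[C>G]T	0.002032520325	0.01102941176	0.001482213439	0.00262605042
A[C>T]A	0.002032520325	0.01164215686	0.001482213439	0.00262605042
A[C>T]C	0.002032520325	0.01225490196	0.001482213439	0.00262605042
A[C>T]G	0.2032520325	0.008578431373	0.001482213439	0.00262605042
A[C>T]T	0.002032520325	0.009191176471	0.001482213439	0.00262605042
C[C>T]A	0.002032520325	0.009803921569	0.1086956522	0.00262605042
C[C>T]C	0.002032520325	0.01041666667	0.1086956522	0.00262605042
C[C>T]G	0.2032520325	0.01102941176	0.1086956522	0.00262605042
C[C>T]T	0.002032520325	0.01164215686	0.1086956522	0.00262605042
G[C>T]A	0.002032520325	0.01225490196	0.001482213439	0.00262605042
G[C>T]C	0.002032520325	0.008578431373	0.001482213439	0.00262605042
G[C>T]G	0.2032520325	0.009191176471	0.001482213439	0.00262605042
G[C>T]T	0.002032520325	0.009803921569	0.001482213439	0.00262605042
T[C>T]A	0.002032520325	0.01041666667	0.1086956522	0.00262605042
T[C>T]C	0.002032520325	0.01102941176	0.1086956522	0.00262605042
T[C>T]G	0.2032520325	0.01164215686	0.1086956522	0.00262605042
T[C>T]T	0.002032520325	0.01225490196	0.1086956522	0.00262605042
A[T>A]A	0.002032520325	0.008578431373	0.001482213439	0.00262605042
A[T>A]C	0.002032520325	0.009191176471	0.001482213439	0.00262605042
A[T>A]G	0.002032520325	0.009803921569	0.001482213439	0.00262605042
A[T>A]T	0.002032520325	0.01041666667	0.001482213439	0.00262605042
C[T>A]A	0.002032520325	0.01102941176	0.001482213439	0.00262605042
C[T>A]C	0.002032520325	0.01164215686	0.001482213439	0.00262605042
C[T>A]G	0.002032520325	0.01225490196	0.001482213439	0.00262605042
C[T>A]T	0.002032520325	0.008578431373	0.001482213439	0.00262605042
G[T>A]A	0.002032520325	0.009191176471	0.001482213439	0.00262605042
G[T>A]C	0.002032520325	0.009803921569	0.001482213439	0.00262605042
G[T>A]G	0.002032520325	0.01041666667	0.001482213439	0.00262605042
G[T>A]T	0.002032520325	0.01102941176	0.001482213439	0.00262605042
T[T>A]A	0.002032520325	0.01164215686	0.001482213439	0.00262605042
T[T>A]C	0.002032520325	0.01225490196	0.001482213439	0.00262605042
T[T>A]G	0.002032520325	0.008578431373	0.001482213439	0.00262605042
T[T>A]T	0.002032520325	0.009191176471	0.001482213439	0.00262605042
A[T>C]A	0.002032520325	0.009803921569	0.001482213439	0.00262605042
A[T>C]C	0.002032520325	0.01041666667	0.001482213439	0.00262605042
A[T>C]G	0.002032520325	0.01102941176	0.001482213439	0.00262605042
A[T>C]T	0.002032520325	0.01164215686	0.001482213439	0.00262605042
C[T>C]A	0.002032520325	0.01225490196	0.001482213439	0.00262605042
C[T>C]C	0.002032520325	0.008578431373	0.001482213439	0.00262605042
C[T>C]G	0.002032520325	0.009191176471	0.001482213439	0.00262605042
C[T>C]T	0.002032520325	0.009803921569	0.001482213439	0.00262605042
G[T>C]A	0.002032520325	0.01041666667	0.001482213439	0.00262605042
G[T>C]C	0.002032520325	0.01102941176	0.001482213439	0.00262605042
G[T>C]G	0.002032520325	0.01164215686	0.001482213439	0.00262605042
G[T>C]T	0.002032520325	0.01225490196	0.001482213439	0.00262605042
T[T>C]A	0.002032520325	0.008578431373	0.001482213439	0.00262605042
T[T>C]C	0.002032520325	0.009191176471	0.001482213439	0.00262605042
T[T>C]G	0.002032520325	0.009803921569	0.001482213439	0.00262605042
T[T>C]T	0.002032520325	0.01041666667	0.001482213439	0.00262605042
A[T>G]A	0.002032520325	0.01102941176	0.001482213439	0.00262605042
A[T>G]C	0.002032520325	0.01164215686	0.001482213439	0.00262605042
A[T>G]G	0.002032520325	0.01225490196	0.001482213439	0.00262605042
A[T>G]T	0.002032520325	0.008578431373	0.001482213439	0.00262605042
C[T>G]A	0.002032520325	0.009191176471	0.001482213439	0.00262605042
C[T>G]C	0.002032520325	0.009803921569	0.001482213439	0.00262605042
C[T>G]G	0.002032520325	0.01041666667	0.001482213439	0.00262605042
C[T>G]T	0.002032520325	0.01102941176	0.001482213439	0.00262605042
G[T>G]A	0.002032520325	0.01164215686	0.001482213439	0.00262605042
G[T>G]C	0.002032520325	0.01225490196	0.001482213439	0.00262605042
G[T>G]G	0.002032520325	0.008578431373	0.001482213439	0.00262605042
G[T>G]T	0.002032520325	0.009191176471	0.001482213439	0.00262605042
T[T>G]A	0.002032520325	0.009803921569	0.001482213439	0.00262605042
T[T>G]C	0.002032520325	0.01041666667	0.001482213439	0.00262605042
T[T>G]G	0.002032520325	0.01102941176	0.001482213439	0.00262605042
T[T>G]T	0.002032520325	0.01164215686	0.001482213439	0.00262605042
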