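# Calibrated default parameters of the hippocampo-thalamo-cortical
# neural-mass model. All values are this package's own calibration,
# chosen so that the isolated subnetworks generate their characteristic
# NREM rhythms and the coupled network operates in the coupled
# slow-wave / spindle / SWR regime (see the methods vignette).
#
# Units: V*, g in mV; tau in s; rates R in Hz; J in mV.s (effective
# drive is N * P * J * r, in mV/s); c, dc in adaptation units; u, b in mA.

# --- global sigmoid firing rate (Eq. 1 populations) ---
r0 = 0.1
r1 = 70

# --- sigmoid sharpness g and threshold Vstar per population ---
g.e.CA3 = 1
Vstar.e.CA3 = 4
g.i.CA3 = 1
Vstar.i.CA3 = 4
g.e.CA1 = 0.4
Vstar.e.CA1 = 3
g.i.CA1 = 0.4
Vstar.i.CA1 = 3
g.e.CX = 1
Vstar.e.CX = 4.613
g.i.CX = 1
Vstar.i.CX = 6
g.e.CXp = 1
Vstar.e.CXp = 4.433
g.i.CXp = 1
Vstar.i.CXp = 6
g.e.REU = 1
Vstar.e.REU = 3

# --- thalamic tonic/burst rates (MD, TRN) ---
RT.MD = 70
VT.MD = 4
gT.MD = 1
RB.MD = 250
VB.MD = 2.5
gB.MD = 0.4
L.MD = 0.03
RT.TRN = 70
VT.TRN = 5
gT.TRN = 1.2
RB.TRN = 250
VB.TRN = 8
gB.TRN = 1.2
L.TRN = 0.03

# --- burst drive and u dynamics ---
f.max.MD = -400
f.th.MD = 60
q.MD = 4
tau.u.MD = 0.9
b.MD = -450
Vb.MD = -0.1
f.max.TRN = 0
f.th.TRN = 30
q.TRN = 5
tau.u.TRN = 0.1
b.TRN = -200
Vb.TRN = 0

# --- dendritic spike-frequency adaptation ---
gc = 2
cstar = 10
tau.c = 0.65
dc.CA3 = 0.12
dc.CA1 = 0.0005
dc.CX = 0.018
dc.CXp = 0.019

# --- membrane time constants (s) ---
tau.e.CA3 = 0.03
tau.i.CA3 = 0.01
tau.e.CA1 = 0.012
tau.i.CA1 = 0.012
tau.e.CX = 0.03
tau.i.CX = 0.01
tau.e.CXp = 0.03
tau.i.CXp = 0.01
tau.MD = 0.02
tau.TRN = 0.02
tau.REU = 0.18

# --- neuron counts ---
N.e.CA3 = 100
N.i.CA3 = 25
N.e.CA1 = 100
N.i.CA1 = 25
N.e.CX = 100
N.i.CX = 25
N.e.CXp = 100
N.i.CXp = 25
N.e.MD = 100
N.i.TRN = 100
N.e.REU = 100

# --- connection probabilities ---
P.ee.CA3 = 0.2
P.ie.CA3 = 0.2
P.ei.CA3 = 0.2
P.ii.CA3 = 0.2
P.ie.CA1 = 0.2
P.ei.CA1 = 0.2
P.ii.CA1 = 0.2
P.ee.CA3_CA1 = 0.1
P.ei.CA3_CA1 = 0.1
P.ee.REU_CA1 = 0.1
P.ei.REU_CA1 = 0.1
P.ee.CX = 0.2
P.ie.CX = 0.2
P.ei.CX = 0.2
P.ii.CX = 0.2
P.ee.CXp_CX = 0.1
P.ei.CXp_CX = 0.1
P.ee.REU_CX = 0.1
P.ei.REU_CX = 0.1
P.ee.CA1_CX = 0.1
P.ei.CA1_CX = 0.1
P.ee.CXp = 0.2
P.ie.CXp = 0.2
P.ei.CXp = 0.2
P.ii.CXp = 0.2
P.ee.CX_CXp = 0.1
P.ei.CX_CXp = 0.1
P.ee.MD_CXp = 0.1
P.ei.MD_CXp = 0.1
P.ie.TRN_MD = 0.2
P.ee.CXp_MD = 0.1
P.ii.TRN = 0.2
P.ei.MD_TRN = 0.2
P.ei.CXp_TRN = 0.1
P.ie.TRN_REU = 0.1
P.ee.CX_REU = 0.1
P.ee.CA1_REU = 0.1

# --- synaptic strengths J (per connection) ---
J.ee.CA3 = 0.8
J.ie.CA3 = 1.6
J.ei.CA3 = 0.2
J.ii.CA3 = 0.2
J.ie.CA1 = 7
J.ei.CA1 = 1.75
J.ii.CA1 = 0.1
J.ee.CA3_CA1 = 0.9
J.ei.CA3_CA1 = 0.3
J.ee.REU_CA1 = 0.8
J.ei.REU_CA1 = 0.03
J.ee.CX = 0.7395
J.ie.CX = 3.97
J.ei.CX = 0.45
J.ii.CX = 0.2
J.ee.CXp_CX = 0.3
J.ei.CXp_CX = 0.02
J.ee.REU_CX = 0.03
J.ei.REU_CX = 0.02
J.ee.CA1_CX = 0.3
J.ei.CA1_CX = 0.03
J.ee.CXp = 0.7395
J.ie.CXp = 4.33
J.ei.CXp = 0.45
J.ii.CXp = 0.2
J.ee.CX_CXp = 0.05
J.ei.CX_CXp = 0.02
J.ee.MD_CXp = 0.15
J.ei.MD_CXp = 0.02
J.ie.TRN_MD = 0.7
J.ee.CXp_MD = 0.02
J.ii.TRN = 0.01
J.ei.MD_TRN = 0.12
J.ei.CXp_TRN = 0.4
J.ie.TRN_REU = 0.005
J.ee.CX_REU = 0.35
J.ee.CA1_REU = 0.08

# --- scaling of the two CA1<->reuniens E-E pathways (sweep axes) ---
alpha.CA1_REU = 1
alpha.REU_CA1 = 1

# --- external tonic drives (mV/s), 0 in the default NREM configuration ---
I.CA3 = 0
I.CA1 = 0
I.CX = 0
I.CXp = 0
I.MD = 0
I.TRN = 0
I.REU = 0

# --- background input noise for the NREM session analyses (mV per
# sqrt(s) on the membrane-potential states; the integrator itself
# defaults to the deterministic equations when no level is requested) ---
noise.sd = 2
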