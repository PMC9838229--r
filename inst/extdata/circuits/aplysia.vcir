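# Classical conditioning of the aplysia withdrawal reflex.
# The us pathway to the motor thread is open from the start; the cs pathway
# is closed and gets potentiated by an ltp interneuron acting as a
# coincidence detector between cs and us (temporal pairing).
circuit aplysia
stream s
node sensor s s_cs cs
node sensor s s_us us
node effector s motor motor(X)
edge synapse s_us motor w=1 payload=motor(us)
edge synapse s_cs motor w=0 payload=motor(cs)
edge modulation s_us s_cs>motor plasticity=ltp
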