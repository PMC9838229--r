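# Sensory-motor substage 3: visual tracking of a moving object.
# move(obj(P,X)) sets the focus of attention to an expectation at X+1
# (sustained two cycles, modeling a saccade's anticipation). The next
# sensation see(obj(Q,X+1)) is discriminated by an ordered choice:
#   cont   - the expected object is seen at the expected position
#   divert - another item (e.g. an occluding screen) is seen there
# A visible halt while tracking drives a grasp at X+1; an occlusion drives
# a look at the occluding item. Short-term potentiations from the
# expectation open the discrimination paths for the attention span.
circuit tracking
stream main
node sensor main s_move move(obj(P,X))
node internal main expect expect(obj(P,X+1)) ttl=2
node sensor main s_see see(obj(Q,X+1))
node internal main cont cont(obj(P,X+1)) ttl=2
node internal main divert divert(obj(Q,X+1))
node sensor main s_halt halt(T)
node effector main grasp grasp(obj(P,X+1))
node effector main look look(obj(Q,X+1))
edge synapse s_move expect
edge conj expect cont w=0 plasticity=stp:expect:2 choice=attend
edge conj s_see cont as=see(obj(P,X+1))
edge conj expect divert w=0 plasticity=stp:expect:2 as=expect(obj(P0,X+1)) choice=attend
edge conj s_see divert
edge synapse divert look
edge conj cont grasp
edge conj s_halt grasp as=halt(obj(P,X+1))
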